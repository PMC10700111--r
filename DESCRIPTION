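Package: orthotrim
Title: Orthology Inference and Phylogeny-Aware Alignment Curation for
    Dense Sets of Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Orthotrim", "Developers", email = "orthotrim@example.org",
           role = c("aut", "cre"))
Description: Infers orthologous groups of proteins from reciprocal-best-hit
    graphs built out of merged BLAST high-scoring segment pairs, clusters
    them by k-clique percolation with a k-core fallback, organises groups
    into gene-level units, selects representative isoforms with tree-weighted
    binary gap profiles, refines alignments by anchored realignment of
    diverged regions, and trims poorly supported alignment regions with
    phylogenetic hidden Markov models whose emissions combine a two-state
    substitution process on the species tree, a tip-level annotation-error
    jump process, and a beta-binomial gap-stickiness component.  Includes a
    synthetic-scenario generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
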