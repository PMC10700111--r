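---
title: "orthotrim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthotrim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotrim)
```

# The problem

When many closely related, densely sampled genomes are annotated by
automated pipelines, two things happen at once.  First, orthologous
proteins identify each other as reciprocal best hits across almost every
genome pair, so the hit graph becomes extremely redundant and classical
clustering rules (connected components, triangle clustering, Markov flow)
that need only one or two edges to admit a node become too permissive.
Second, the annotations themselves are noisy at the residue level: gene
models include spurious segments, miss exons, or truncate sequences, and
those defects propagate directly into multiple sequence alignments as
over-aligned insertions, phylogenetically discordant gap blocks, and
long runs of missing residues.

`orthotrim` implements a pipeline that exploits the redundancy rather
than suffering from it: a stringent, tunable clustering of the
reciprocal-best-hit graph, gene-aware organisation of the resulting
groups, profile-based selection of one representative isoform per gene,
anchored realignment of diverged regions, and a phylogenetic hidden
Markov model (phylo-HMM) that trims alignment regions whose gap patterns
are not supported by the species tree.

# From HSP tables to a hit graph

The unit of input is the HSP: one local alignment between a query and a
target protein, with intervals, a bit score and an E-value.  All residue
intervals are handled as 0-based half-open; the BLAST tabular reader
converts from BLAST's 1-based closed coordinates at parse time.

*De-duplication.*  Within each species, the first accession seen for
each (gene, sequence) pair is that pair's representative; distinct
isoform sequences of a gene are all retained, and an identical sequence
annotated under two genes is retained for each gene.

*Best-gene extraction.*  For one query against one target species, HSPs
are grouped by target protein and groups are ranked by their top bit
score.  Groups are emitted in rank order until a group's parent gene is
not the top-ranked gene; if several genes tie at the top, emission stops
at the first group whose gene matches none of the tied genes.  This is a
best-hit criterion applied at the level of genes rather than proteins.

*HSP merging.*  All HSPs of a (query, target) pair become one hit in two
passes over descending bit score.  Pass 1 greedily marks an HSP
*disjoint* if its query interval overlaps no previously marked disjoint
HSP — greedy by design, preferring a few long HSPs over many fragments
even when a weighted-interval-scheduling optimum would score higher (the
test suite documents instances where greedy is suboptimal).  Pass 2
seeds the *compatible* set with the disjoint set, then admits an HSP if
its overlap with **every** already-compatible HSP is at most 50% of the
length of either interval (both conditions must hold).  The hit carries
`disjoint_score` (sum of disjoint bit scores) and `query_coverage` (the
fraction of the query covered by the union of compatible intervals).
Overlap is assessed on query coordinates; the choice of coordinate
system is not forced by anything upstream and is recorded here as a
package decision.

*Filters.*  A best hit (arg-max of `disjoint_score`, ties to the
lexicographically smallest target) survives only with coverage ≥ 0.5
(inclusive), and an undirected edge is created only when both directions
survive (reciprocity).  The edge score is the larger of the two directed
disjoint scores — the paper-silent symmetrisation that preserves the
stronger evidence.  Thresholds stated as minima are inclusive; the
paralog criterion below ("exceeds") is strict.

*Paralogs.*  Self-search output is processed without the best-gene
filter; per query and target gene the top isoform's hit is kept, and a
pair is paralogous iff its disjoint score strictly exceeds the query's
maximum inter-genome best-hit score (−∞ when the query has none) and the
overlap/reciprocity filters pass.

# Clustering

Orthologous groups are the k-clique percolation communities of the hit
graph: unions of k-cliques connected through k-cliques sharing k−1
nodes.  `clique_percolation()` enumerates maximal cliques (igraph) and
accretes them progressively into communities — a clique joins any
community with which one of its member cliques shares at least k−1
nodes, merging communities when a clique bridges several.  This is
equivalent to connecting maximal cliques of size ≥ k that share ≥ k−1
nodes, which the test suite verifies against a brute-force k-clique
adjacency oracle.  k = 2 reduces to connected components and k = 3 to
triangle percolation; the default k = 4 is a compromise between
sensitivity and cluster tightness.  Communities may overlap in nodes,
and overlapping clusters are retained as-is.

Pathological components (dense clique fields, e.g. large tandem
families) can stall either phase; after a wall-clock timeout (default
90 s per phase) — or, deterministically in tests, a maximal-clique
budget — the component falls back to the (k−1)-core: connected
components of the maximal subgraph of minimum degree k−1, the internal
degree of a k-clique's nodes.

Groups are then augmented with paralogs (one step only: pairs touching
original members; no transitive closure), grouped into gene-level units
(edges between orthogroups whose parent-gene sets overlap by at least
half the smaller set; components are the gene groups), and filtered to
single-copy groups: no species with two parent genes, user-supplied
diversity criteria met (minimum species counts per named set — supplied
by configuration, since no canonical sets ship with the package), and
one orthogroup per gene group, ranked by species count then total edge
score.

# Tree-derived weights and binary profiles

Closely related species are not independent observations.  All weighted
statistics use species weights derived from the Brownian-motion
covariance implied by the rooted species tree: `cov(i, j)` is the shared
root-to-tip path length of tips i and j, and the weights are the
minimum-variance unbiased combination `w ∝ C⁻¹1` (Altschul–Carroll–Lipman),
normalised to sum 1 and computed through an SVD pseudo-inverse so that
degenerate trees (zero-length stars) fall back to equal weights.  This is
the package's single largest interpretive choice: the source framework is
named only as a Gaussian process on the tree, without formulas.  A
consequence worth knowing: for two tips with unequal branch lengths the
weights are *unequal* — the tip with the smaller variance gets more
weight — and this is intended.  The rare pathological tree that drives a
weight non-positive is handled by clamping to a small positive value and
renormalising.

A *binary profile* codes an alignment into gap/non-gap symbols, groups
rows by gene (a species' weight is split evenly over its genes), and per
column credits the group's weight to non-gap if *any* of its rows is
non-gap.  Counts start at a pseudocount of 0.005 per symbol per column
so no sequence scores −∞.  Each coded row is scored by
`Σ_col log(count(symbol)/total)`, and the top-scoring row per gene is
that gene's representative (ties to the smallest accession, making the
choice order-independent).  The construction deliberately favours the
isoform with the fewest gaps that best matches the consensus.

The *gap profile* used by refinement and curation is the weighted gap
fraction per column of a single-copy alignment (one row per species).

# Anchored refinement

An alignment produced with a strong over-alignment correction is
thresholded at weighted non-gap fraction > 0.5 (strictly), the boolean
mask is closed morphologically with a flat structuring element of size 3
(dilation padding FALSE, erosion padding TRUE, so closing is extensive
and idempotent — applied once; idempotence makes repetition moot), and
runs of at least 10 TRUE columns become conserved anchors.  Each
complementary diverged span — including spans at the alignment edges —
is degapped row-wise, realigned through an adapter with a weaker
correction (`a_max` 0.4 against 0.7 for the initial alignment), and
stitched back in place.  The production adapter shells out to MAFFT with
`--globalpair --maxiterate 1000 --thread 1 --anysymbol --allowshift
--leavegappyregion --unalignlevel <a_max>`; the test suite uses a
deterministic in-package mock so it never depends on an external
aligner's version.  Two hard invariants are enforced at run time and
verified per fixture: degapping any row before and after refinement
yields identical residues, and conserved spans are bitwise unchanged.

# The phylo-HMM

Alignment columns are coded gap/non-gap and modelled by a 4-state HMM
whose per-state emission has three components:

1. **Phylogenetic component.**  A two-state CTMC with rates `rate01`
   (gap → non-gap) and `rate10` on the species tree; the transition
   matrix over a branch has the closed form
   `P(t) = Π + exp(−(r01+r10) t)(I − Π)` with Π the stationary
   projector.  Column likelihoods come from Felsenstein pruning
   (vectorised across columns), with the stationary distribution at the
   root.  Over all 2ⁿ tip columns the likelihood sums to one, which the
   tests check exhaustively.
2. **Tip jump process.**  Annotation can add or delete segments
   independently of evolution, so each tip observation is an
   error mixture: with probability ε the observed symbol is redrawn
   Bernoulli(q) regardless of the latent state,
   `P(obs s | latent x) = (1−ε)·1[s=x] + ε·Bern_q(s)`.  Placing the jump
   at the observation layer (rather than inside the CTMC) is a package
   choice; the source architecture does not pin it down.
3. **Gap stickiness.**  A beta-binomial on the number of tips whose
   symbol is unchanged from the previous column; the first column omits
   the term (it is defined on column pairs).

The three components jointly over-determine consecutive columns, so the
emission is treated as an unnormalised product score for decoding, and
`simulate_phylo_hmm()` samples from the phylogenetic and jump components
only — stickiness is emergent, not separately sampled.

The four states are: (1) phylogenetically concordant, mostly non-gap;
(2) a stable gap pattern discordant with the tree (conserved skipped
exons); (3) poorly supported segments, mostly gap with a few non-gap
rows; (4) diverged/noisy columns with fast turnover and low stickiness.
Only three region types are described by the source narrative; the
fourth state is this package's definition, and trimming acts only on
states 2 and 3.  Because the published trained parameters are not
available, `default_insertion_model()` ships hand-set parameters
appropriate for trees scaled to height ≈ 1.  One default deserves
comment: state 1's jump probability is 0.12, large enough that a
single-tip stretch of gaps (a missing segment) is absorbed by the
annotation-noise mixture instead of being mislabelled as state 2 — a
requirement of the state semantics, since missing data is per-sequence,
not columnar.

The generic engine (`forward_backward()`) uses scaled recursions with a
per-position max shift; posteriors sum to one per position and the total
likelihood matches brute-force path enumeration to 1e-10 in the tests.
Emission models plug in behind a log-emission-matrix contract, so the
engine is reusable.

*Missing-data model.*  A 2-state HMM decoded per sequence, sharing the
phylogenetic emission architecture but scoring the **posterior** of the
focal tip's observed symbol given all other tips,
`P(obs_focal | others) = P(column)/Σ_s P(column with focal = s)`,
computed by two pruning passes.  This turns "how surprising is this gap
given the rest of the column?" into an emission.

*Discriminative training.*  Maximum-likelihood parameters yield posterior
curves that toggle too rapidly, so training minimises the per-position
cross-entropy between the posterior decoding and manual labels (the
objective formula is a package choice; the source names only the training
style).  The search is derivative-free (Nelder–Mead) over an
unconstrained reparameterisation — logits for probabilities, log-rates
for the CTMC — run in rounds so the reported loss trace is monotone
non-increasing; the trained model is returned only if it strictly
improves on the start.

# Converting posteriors into trims

*Region definition.*  A high cutoff defines seed runs on the posterior
curve.  Each seed endpoint expands outward while the posterior stays
above a floor **and** the forward-difference derivative stays above a
floor, and inward (clamped at the seed) while the derivative stays above
a third floor; within the resulting window the boundary is the step
maximising |Δ posterior| × |Δ gap profile|, so boundaries snap to where
model confidence and the observed gap pattern change together.
Overlapping regions merge.  The derivative is the forward difference —
the simplest consistent discretisation — and when the inward window
would cross the outward one it is clamped at the seed endpoint.

*State 3 (segments).*  The state 3 posterior is first zeroed on columns
with gap profile ≤ 0.1, breaking long poorly supported segments aligned
over conserved columns into separate regions.  Regions use cutoffs
0.75/1e-3 and derivative floors 0.001.  Per region, the weighted mean
non-gap count μ is computed excluding the 5 sequences with the most
non-gap symbols, capped at 2; with `p = 1/(μ+1)` and α = 0.01 the
geometric cutoff is `k = log(α)/log(1−p) − 1` (≈ 10.3578 at μ = 2), and
every sequence with count ≥ k (real-valued comparison, no rounding) has
its non-gap symbols replaced by gaps in the region.  At μ = 0 the limit
k = −1 applies, trimming any sequence with non-gap content.  Trimming
region by region is what lets a conserved column survive even when one
sequence's spurious segment crosses it.

*State 2 (columns).*  The state 2 posterior plus the state 3 posterior
zeroed inside already-trimmed state 3 regions (catching regions
intermediate between the two states) is segmented with a high cutoff of
0.9; every column of each region is deleted.

*Missing segments.*  Seeds are positions with missing-state posterior ≥
0.75 **restricted to gap positions** — a present residue can never
itself be missing, and without the restriction posterior smoothing can
push a seed one or two columns into flanking residues.  Seeds expand
outward across gaps until the first non-gap symbol or a posterior below
0.05, merge, and serialise as 0-based half-open slice lists
(`"start0-stop0,start1-stop1"`).

A caveat the tests document: applying the state 3 trimmer twice is *not*
idempotent for arbitrary count configurations, because trimming changes
which five sequences are excluded from μ.  It is idempotent for the
configuration the trimmer targets — one long carrier over near-zero
background — and the suite asserts exactly that.

# Species-tree support

Meta-alignments are built by sampling columns uniformly **with
replacement** from the global pool of eligible columns across all input
alignments (sampling per-alignment-first is the alternative; the global
pool was chosen).  Eligibility filters: maximum gap fraction (0, 0.5
or 1) and optionally no invariant columns, where "invariant" means all
non-gap symbols identical (an all-gap column counts as invariant).
Reverse translation expands each residue to its codon and each gap to
three gaps, tolerates one trailing stop codon, and *rejects* (flags, not
errors) alignments whose CDS translation disagrees with the degapped
protein.  Consensus trees are built from bipartition frequencies:
majority mode keeps bipartitions in strictly more than half the trees;
loose mode adds compatible bipartitions greedily in descending
frequency — ties to the lexicographically smallest bipartition — until
the tree is fully resolved, preventing multifurcations when supports
fall below 50%.  Node labels carry the bipartition percentage.

# The synthetic world

`generate_scenario()` is first-class, tested code, and its defaults are
the package's reference validation world: 8 species, 20 single-copy
genes, 2 planted paralog pairs, 3 spurious 30-residue insertions, 2
missing segments of 25 residues, on a coalescent species tree rescaled
to height 1.  Sequences follow an identity model — a random ancestral
protein per gene, substituted per species at 0.15 per site scaled by tip
depth — because only score *ordering* matters to the pipeline.  Each
protein tracks the core coordinate of every residue, and HSPs are
emitted per maximal homologous segment (the way a local search reports
separate HSPs around indels), scored 2 × matches plus Gaussian noise
(σ = 0.5) with E-value a deterministic decreasing function of score;
weak distractor HSPs to the wrong gene exercise the best-gene criterion.
Planted defects appear consistently in the sequences, the block-model
alignments (insertions own their columns), and the per-column /
per-position labels.

What the generator does **not** emulate: realistic substitution-model
evolution, alignment uncertainty (the "initial alignments" are exact by
construction), compositional biases, fragmented assemblies, or
inter-family homology.  A green end-to-end test therefore establishes
that every decision rule fires correctly on data satisfying the
pipeline's assumptions — not that the pipeline is robust to aligner
error, which is precisely what the refinement and curation stages exist
to mitigate on real data.

# Numerical choices and limitations

- E-value filter ≤ 1e-10; coverage ≥ 0.5; paralog comparison strict >;
  seed cutoffs inclusive.
- Pruning partials are rescaled per column when magnitudes leave
  [1e-150, 1e150]; the HMM uses scaled (not log-space) recursions.
- Log base for profile scores is natural; scores are only ever compared
  within one profile.
- Gap symbols are `-` and `.`; everything else, including `X`, is
  non-gap.
- Tie-breaks are lexicographic throughout (best hits, representatives,
  group ids, loose-consensus bipartitions) for determinism.
- The k-core fallback's degree convention (≥ k−1) is a package choice
  aligning the fallback with percolation's clique size.
- Known limitations: emissions are binary (no amino-acid alphabet), no
  splice-aware states, no realignment after trimming, and tree inference
  itself is out of scope — trees are consumed as Newick, never fitted.

```{r example, eval = FALSE}
# end-to-end sketch on the reference synthetic world
sc  <- generate_scenario(scenario_config(), seed = 7)
res <- infer_orthogroups(sc$proteins, sc$hsps, sc$self_hsps, k = 4)
w   <- gp_species_weights(sc$tree)
cur <- curate_alignment(sc$alignments[["g03"]], sc$aln_meta[["g03"]],
                        default_insertion_model(), sc$tree, w)
apply_trims(sc$alignments[["g03"]], cur$actions)
```
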