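# End-to-end orchestration: scenario (or parsed files) -> edges ->
# orthogroups -> gene groups -> single-copy selection; plus the default
# insertion / missing-data model parameter sets shipped with the package.

#' Run orthology inference on a scenario or parsed inputs
#'
#' @param proteins data.frame with \code{accession, gene, species,
#'   sequence}.
#' @param hsps Inter-genome HSP table (raw schema, see
#'   [read_blast_tab()]).
#' @param self_hsps Self-search HSP table (may have zero rows).
#' @param k Clique-percolation parameter.
#' @param evalue_cutoff E-value threshold.
#' @param timeout,max_cliques Passed to [cluster_hit_graph()].
#' @return List with \code{records} (de-duplicated proteins),
#'   \code{edges}, \code{paralog_pairs}, \code{graph}, \code{groups}
#'   (annotated, paralog-augmented) and \code{gene_groups}.
#' @export
infer_orthogroups <- function(proteins, hsps, self_hsps = NULL, k = 4L,
                              evalue_cutoff = 1e-10, timeout = 90,
                              max_cliques = Inf) {
  records <- deduplicate_proteins(proteins)
  gene_map <- records[, c("species", "gene", "accession")]
  hsps <- hsps[hsps$qseqid %in% records$accession &
                 hsps$sseqid %in% records$accession, , drop = FALSE]
  hsps <- annotate_hsp_genes(hsps, gene_map)
  best <- collect_best_hits(hsps, evalue_cutoff)
  edges <- apply_hit_filters(best)
  pairs <- data.frame(a = character(0), b = character(0),
                      score = numeric(0))
  if (!is.null(self_hsps) && nrow(self_hsps)) {
    self_hsps <- self_hsps[self_hsps$qseqid %in% records$accession &
                             self_hsps$sseqid %in% records$accession, ,
                           drop = FALSE]
    self_hsps <- annotate_hsp_genes(self_hsps, gene_map)
    q <- vapply(best, `[[`, character(1), "query")
    s <- vapply(best, `[[`, numeric(1), "disjoint_score")
    inter_max <- tapply(s, q, max)
    pairs <- detect_paralogs(self_hsps, inter_max,
                             evalue_cutoff = evalue_cutoff)
  }
  meta <- records[, c("accession", "species", "gene")]
  graph <- build_hit_graph(edges, meta)
  groups <- cluster_hit_graph(graph, k = k, timeout = timeout,
                              max_cliques = max_cliques)
  groups <- add_paralogs(groups, pairs)
  groups <- lapply(groups, annotate_group, meta = meta)
  gene_groups <- group_by_gene(groups)
  list(records = records, edges = edges, paralog_pairs = pairs,
       graph = graph, groups = groups, gene_groups = gene_groups)
}

#' Rand index between two partitions
#'
#' @param labels_a,labels_b Cluster labels over the same elements.
#' @return The Rand index in [0, 1].
#' @export
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2L) return(1)
  same_a <- outer(labels_a, labels_a, "==")
  same_b <- outer(labels_b, labels_b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

#' Default insertion phylo-HMM
#'
#' Four hidden states over binary (gap / non-gap) alignment columns:
#' state 1 = phylogenetically concordant, mostly non-gap; state 2 =
#' stable gap pattern discordant with the tree (skipped exon), dominated
#' by the tip jump process; state 3 = poorly supported segments, mostly
#' gap with a few non-gap sequences; state 4 = diverged/noisy columns
#' with fast symbol turnover and low stickiness.  Parameters are the
#' package's hand-set defaults (suitable for trees scaled to height about
#' 1); retrain with [train_discriminative()] for other data.
#'
#' @return An \code{hmm_spec}.
#' @export
default_insertion_model <- function() {
  states <- c("1", "2", "3", "4")
  start <- c(0.85, 0.05, 0.05, 0.05)
  trans <- rbind(c(0.97, 0.01, 0.01, 0.01),
                 c(0.02, 0.96, 0.01, 0.01),
                 c(0.02, 0.01, 0.96, 0.01),
                 c(0.02, 0.01, 0.01, 0.96))
  em <- list(
    # state 1 tolerates sporadic single-tip gaps through the jump process
    # (annotation noise), so isolated missing stretches in one sequence do
    # not masquerade as discordant regions
    emission_params(binary_ctmc(0.95, 0.05), tip_jump(0.12, 0.85),
                    stickiness_params(10, 1)),
    emission_params(binary_ctmc(0.05, 0.05), tip_jump(0.9, 0.5),
                    stickiness_params(20, 1)),
    emission_params(binary_ctmc(0.2, 1.8), tip_jump(0.05, 0.5),
                    stickiness_params(10, 1)),
    emission_params(binary_ctmc(2, 2), tip_jump(0.3, 0.5),
                    stickiness_params(1, 1)))
  hmm_spec(states, start, trans, em)
}

#' Default missing-data phylo-HMM
#'
#' Two states ("not_missing", "missing") sharing the insertion model's
#' phylogenetic emission architecture but scored as the posterior
#' probability of the focal tip's symbol given all other tips.
#'
#' @return An \code{hmm_spec}.
#' @export
default_missing_model <- function() {
  states <- c("not_missing", "missing")
  start <- c(0.95, 0.05)
  trans <- rbind(c(0.98, 0.02),
                 c(0.02, 0.98))
  em <- list(
    emission_params(binary_ctmc(0.95, 0.05), tip_jump(0.02, 0.9),
                    stickiness_params(1, 1)),
    emission_params(binary_ctmc(0.02, 1.98), tip_jump(0.02, 0.1),
                    stickiness_params(1, 1)))
  hmm_spec(states, start, trans, em)
}

#' Report missing segments for every sequence of an alignment
#'
#' Decodes each row with the missing-data model and converts posteriors
#' into merged segments (see [call_missing()]).
#'
#' @param aln Named character vector (single-copy alignment).
#' @param meta Row metadata (accession, species).
#' @param spec Missing-data \code{hmm_spec} (state "missing" present).
#' @param tree Rooted \code{phylo} over the species.
#' @return Named list of segment data.frames, one per accession, plus a
#'   \code{"slices"} attribute with the serialized form.
#' @export
report_missing <- function(aln, meta, spec, tree) {
  baln <- code_binary(aln, meta)
  columns <- baln$mat
  rownames(columns) <- baln$meta$species
  out <- list()
  slices <- character(0)
  for (i in seq_len(nrow(columns))) {
    sp <- rownames(columns)[i]
    acc <- baln$meta$accession[i]
    fb <- decode_missing(spec, tree, columns, sp)
    segs <- call_missing(fb$posterior[, "missing"], columns[i, ])
    out[[acc]] <- segs
    slices[[acc]] <- format_slices(segs)
  }
  attr(out, "slices") <- slices
  out
}
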