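# Processing of homology-search tabular output into a reciprocal-best-hit
# edge list: de-duplication, best-gene HSP extraction, HSP merging, hit
# selection and filtering, and within-genome paralog detection.
#
# Conventions used throughout:
#  * residue intervals are 0-based half-open [start, stop)
#  * HSP tables are data.frames with columns qseqid, sseqid, bitscore,
#    evalue, qstart, qend, sstart, send, qlen, slen (and optionally
#    qgene, sgene added by annotate_hsp_genes)

#' De-duplicate protein records within each species
#'
#' Genes frequently have transcripts differing only in their UTRs, so
#' annotations contain many duplicate protein sequences.  For each
#' (gene, sequence) pair only the first accession seen is retained as the
#' representative; distinct isoform sequences of a gene are all kept, and
#' identical sequences belonging to different genes are kept for each gene.
#'
#' @param records data.frame with columns \code{accession, gene, species,
#'   sequence}.  Input order is preserved and determines representatives.
#' @return The de-duplicated subset of \code{records}.
#' @export
deduplicate_proteins <- function(records) {
  stopifnot(all(c("accession", "gene", "species", "sequence") %in%
                names(records)))
  dup_acc <- duplicated(paste(records$species, records$accession, sep = "\r"))
  if (any(dup_acc)) {
    stop("duplicate accession(s) within a species: ",
         paste(unique(records$accession[dup_acc]), collapse = ", "))
  }
  key <- paste(records$species, records$gene, records$sequence, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Filter HSPs by E-value
#'
#' The search itself is run with a permissive cutoff; a stricter cutoff
#' (default 1e-10) is applied at processing time.  The threshold is
#' inclusive: an HSP at exactly the cutoff is retained.
#'
#' @param hsps HSP data.frame.
#' @param cutoff Maximum E-value, default \code{1e-10}.
#' @return Filtered HSP data.frame.
#' @export
filter_by_evalue <- function(hsps, cutoff = 1e-10) {
  stopifnot(cutoff > 0)
  hsps[hsps$evalue <= cutoff, , drop = FALSE]
}

#' Attach parent-gene annotations to an HSP table
#'
#' @param hsps HSP data.frame.
#' @param gene_map data.frame with columns \code{species, gene, accession}.
#' @return \code{hsps} with added columns \code{qgene, sgene, qspecies,
#'   sspecies}.
#' @export
annotate_hsp_genes <- function(hsps, gene_map) {
  idx <- match(hsps$qseqid, gene_map$accession)
  jdx <- match(hsps$sseqid, gene_map$accession)
  if (anyNA(idx) || anyNA(jdx)) {
    stop("HSP accession(s) missing from gene map")
  }
  hsps$qgene <- gene_map$gene[idx]
  hsps$sgene <- gene_map$gene[jdx]
  hsps$qspecies <- gene_map$species[idx]
  hsps$sspecies <- gene_map$species[jdx]
  hsps
}

#' Extract HSPs belonging to the best-scoring target gene(s)
#'
#' An extension of the best-hit criterion to the level of genes: HSPs for
#' one query against one target species are grouped by target protein,
#' groups are ranked by their top bit score, and groups are emitted in rank
#' order until one whose parent gene is not among the top-ranked gene(s) is
#' reached.  With a tie at the top, iteration stops at the first group whose
#' gene matches none of the tied top genes.
#'
#' @param hsps HSP data.frame for a single query accession and single
#'   target species, annotated with \code{sgene}.
#' @return The subset of \code{hsps} belonging to emitted groups.
#' @export
extract_best_gene_hsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(hsps)
  stopifnot("sgene" %in% names(hsps))
  grp_max <- tapply(hsps$bitscore, hsps$sseqid, max)
  grp_gene <- tapply(hsps$sgene, hsps$sseqid, function(g) g[1L])
  ord <- order(-grp_max, names(grp_max))
  targets <- names(grp_max)[ord]
  top_score <- grp_max[[targets[1L]]]
  top_genes <- unique(grp_gene[names(grp_max)[grp_max == top_score]])
  emitted <- character(0)
  for (t in targets) {
    if (!(grp_gene[[t]] %in% top_genes)) break
    emitted <- c(emitted, t)
  }
  hsps[hsps$sseqid %in% emitted, , drop = FALSE]
}

#' Merge the HSPs of one query-target pair into a hit
#'
#' Two passes in descending bit-score order.  Pass 1 greedily marks HSPs
#' "disjoint" if their query interval overlaps no previously marked disjoint
#' HSP (a deliberate greedy, not optimal, strategy that prefers few long
#' HSPs over many fragments).  Pass 2 seeds the "compatible" set with the
#' disjoint set and then admits remaining HSPs whose overlap with every
#' already-compatible HSP is at most 50% of the length of either interval.
#'
#' @param hsps HSP data.frame for a single (query, target) accession pair.
#' @return A list of class \code{"ortho_hit"} with elements \code{query,
#'   target, hsps} (with logical columns \code{disjoint, compatible}),
#'   \code{disjoint_score} and \code{query_coverage}, or \code{NULL} for
#'   empty input.
#' @export
merge_hsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(NULL)
  stopifnot(length(unique(hsps$qseqid)) == 1L,
            length(unique(hsps$sseqid)) == 1L)
  ord <- order(-hsps$bitscore, hsps$qstart, hsps$sstart)
  hsps <- hsps[ord, , drop = FALSE]
  n <- nrow(hsps)
  disjoint <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in which(disjoint)) {
      if (overlap_len(hsps$qstart[i], hsps$qend[i],
                      hsps$qstart[j], hsps$qend[j]) > 0) {
        ok <- FALSE
        break
      }
    }
    disjoint[i] <- ok
  }
  compatible <- disjoint
  for (i in seq_len(n)) {
    if (compatible[i]) next
    len_i <- hsps$qend[i] - hsps$qstart[i]
    ok <- TRUE
    for (j in which(compatible)) {
      ov <- overlap_len(hsps$qstart[i], hsps$qend[i],
                        hsps$qstart[j], hsps$qend[j])
      len_j <- hsps$qend[j] - hsps$qstart[j]
      if (ov > 0.5 * len_i || ov > 0.5 * len_j) {
        ok <- FALSE
        break
      }
    }
    compatible[i] <- ok
  }
  hsps$disjoint <- disjoint
  hsps$compatible <- compatible
  qlen <- hsps$qlen[1L]
  cov <- interval_union_length(hsps$qstart[compatible],
                               hsps$qend[compatible]) / qlen
  structure(list(query = hsps$qseqid[1L],
                 target = hsps$sseqid[1L],
                 hsps = hsps,
                 disjoint_score = sum(hsps$bitscore[disjoint]),
                 query_coverage = cov),
            class = "ortho_hit")
}

#' @export
print.ortho_hit <- function(x, ...) {
  cat(sprintf("hit %s -> %s: %d HSPs, disjoint score %.1f, coverage %.2f\n",
              x$query, x$target, nrow(x$hsps), x$disjoint_score,
              x$query_coverage))
  invisible(x)
}

#' Select the best hit for a query
#'
#' The best hit is the one with the highest sum of bit scores over disjoint
#' HSPs; ties break to the lexicographically smallest target accession.
#'
#' @param hits List of hits (from [merge_hsps()]) sharing one query.
#' @return A single hit, or \code{NULL} for empty input.
#' @export
select_best_hit <- function(hits) {
  hits <- Filter(Negate(is.null), hits)
  if (length(hits) == 0L) return(NULL)
  scores <- vapply(hits, `[[`, numeric(1), "disjoint_score")
  targets <- vapply(hits, `[[`, character(1), "target")
  ord <- order(-scores, targets)
  hits[[ord[1L]]]
}

#' Apply overlap and reciprocity filters to directed best hits
#'
#' A directed best hit survives only if at least 50% of the query's
#' residues are aligned in compatible HSPs (coverage >= 0.5, inclusive).
#' Surviving hits are then required to be reciprocal: the edge (q, t) is
#' kept only if t's surviving best hit in q's genome is q.  The undirected
#' edge score is the maximum of the two directed disjoint scores.
#'
#' @param best_hits List of hits, one per (query, target-genome) direction.
#' @param min_coverage Inclusive query-coverage threshold, default 0.5.
#' @return data.frame of undirected edges with columns \code{a, b, score}
#'   where \code{a < b} lexicographically.
#' @export
apply_hit_filters <- function(best_hits, min_coverage = 0.5) {
  best_hits <- Filter(Negate(is.null), best_hits)
  keep <- vapply(best_hits, function(h) h$query_coverage >= min_coverage,
                 logical(1))
  best_hits <- best_hits[keep]
  if (length(best_hits) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0)))
  }
  q <- vapply(best_hits, `[[`, character(1), "query")
  t <- vapply(best_hits, `[[`, character(1), "target")
  s <- vapply(best_hits, `[[`, numeric(1), "disjoint_score")
  fwd <- paste(q, t, sep = "\r")
  rev <- paste(t, q, sep = "\r")
  recip <- fwd %in% rev
  q <- q[recip]; t <- t[recip]; s <- s[recip]
  a <- pmin(q, t); b <- pmax(q, t)
  key <- paste(a, b, sep = "\r")
  score <- tapply(s, key, max)
  uk <- !duplicated(key)
  out <- data.frame(a = a[uk], b = b[uk],
                    score = as.numeric(score[key[uk]]),
                    stringsAsFactors = FALSE)
  out <- out[out$a != out$b, , drop = FALSE]
  out[order(out$a, out$b), , drop = FALSE]
}

#' Build directed best hits from an annotated HSP table
#'
#' Convenience driver: filters HSPs by E-value, applies the best-gene
#' criterion per (query, target species), merges HSPs per (query, target)
#' pair and selects the best hit per (query, target genome).
#'
#' @param hsps Annotated HSP data.frame (see [annotate_hsp_genes()]); may
#'   span many queries and target species but each (query, target-species)
#'   block is processed independently.
#' @param evalue_cutoff E-value threshold applied first.
#' @param best_gene Apply the best-gene extraction step (disabled for
#'   self-searches in paralog mode).
#' @return List of hits, one per surviving (query, target genome).
#' @export
collect_best_hits <- function(hsps, evalue_cutoff = 1e-10,
                              best_gene = TRUE) {
  hsps <- filter_by_evalue(hsps, evalue_cutoff)
  if (nrow(hsps) == 0L) return(list())
  blocks <- split(hsps, list(hsps$qseqid, hsps$sspecies), drop = TRUE)
  out <- list()
  for (blk in blocks) {
    if (best_gene) blk <- extract_best_gene_hsps(blk)
    hits <- lapply(split(blk, blk$sseqid), merge_hsps)
    best <- select_best_hit(hits)
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  out
}

#' Detect within-genome paralogous pairs from self-search output
#'
#' Self-search HSPs are merged without the best-gene criterion; for each
#' query and target gene the highest-scoring isoform's hit is kept.  A
#' (query, target) pair is a paralog pair iff its disjoint score strictly
#' exceeds the maximum inter-genome best-hit score for the query (queries
#' with no inter-genome hits compare against -Inf) and it passes the
#' overlap (coverage >= 0.5) and reciprocity filters.  Self matches
#' (q, q) are excluded.
#'
#' @param self_hsps Annotated HSP table from searching one proteome
#'   against itself.
#' @param inter_max Named numeric: per query accession, the maximum
#'   disjoint score over all inter-genome best hits (missing = -Inf).
#' @param evalue_cutoff E-value threshold.
#' @param min_coverage Coverage threshold for the overlap filter.
#' @return data.frame of unordered pairs with columns \code{a, b, score}.
#' @export
detect_paralogs <- function(self_hsps, inter_max, evalue_cutoff = 1e-10,
                            min_coverage = 0.5) {
  self_hsps <- filter_by_evalue(self_hsps, evalue_cutoff)
  self_hsps <- self_hsps[self_hsps$qseqid != self_hsps$sseqid, , drop = FALSE]
  if (nrow(self_hsps) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0)))
  }
  # Best hit per (query, target gene): merge per target accession, keep the
  # top-scoring isoform within each target gene.
  hits <- list()
  for (blk in split(self_hsps, self_hsps$qseqid)) {
    for (gblk in split(blk, blk$sgene)) {
      merged <- lapply(split(gblk, gblk$sseqid), merge_hsps)
      best <- select_best_hit(merged)
      if (!is.null(best)) hits[[length(hits) + 1L]] <- best
    }
  }
  # Score criterion: strictly greater than the inter-genome maximum.
  keep <- vapply(hits, function(h) {
    m <- if (h$query %in% names(inter_max)) inter_max[[h$query]] else -Inf
    h$disjoint_score > m
  }, logical(1))
  edges <- apply_hit_filters(hits[keep], min_coverage = min_coverage)
  edges
}
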