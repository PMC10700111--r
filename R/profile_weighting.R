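# Binary (gap / non-gap) coding of alignments, tree-derived sequence
# weights, weighted binary profiles, per-gene representative selection and
# weighted gap profiles.

GAP_CHARS <- c("-", ".")

#' Code an alignment into gap / non-gap symbols
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param meta Optional data.frame with columns \code{accession, species,
#'   gene}; rows are matched to \code{names(aln)}.
#' @return An object of class \code{"binary_alignment"}: a list with
#'   \code{mat} (integer matrix, 1 = non-gap, 0 = gap; rownames are
#'   accessions) and \code{meta}.
#' @export
code_binary <- function(aln, meta = NULL) {
  stopifnot(length(aln) > 0L)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, lapply(strsplit(aln, ""), function(ch) {
    as.integer(!(ch %in% GAP_CHARS))
  }))
  rownames(mat) <- names(aln)
  if (!is.null(meta)) {
    idx <- match(names(aln), meta$accession)
    if (anyNA(idx)) stop("alignment row(s) missing from metadata")
    meta <- meta[idx, , drop = FALSE]
  } else {
    meta <- data.frame(accession = names(aln),
                       species = names(aln),
                       gene = names(aln),
                       stringsAsFactors = FALSE)
  }
  structure(list(mat = mat, meta = meta), class = "binary_alignment")
}

#' @export
print.binary_alignment <- function(x, ...) {
  cat(sprintf("binary alignment: %d rows x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Tree-derived species weights
#'
#' Sequence weights from the Brownian-motion (Gaussian-process) covariance
#' implied by a rooted tree with branch lengths, where cov(i, j) is the
#' shared root-to-tip path length of tips i and j.  Weights are the
#' minimum-variance unbiased combination (Altschul-Carroll-Lipman):
#' w proportional to C^+ 1, normalised to sum 1.  Degenerate covariances
#' (e.g. a zero-length star) are handled by the pseudo-inverse and yield
#' equal weights.
#'
#' @param tree A rooted \code{phylo} object with branch lengths >= 0 and
#'   tip labels equal to species ids.
#' @return Named numeric vector of positive weights summing to 1.
#' @export
gp_species_weights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length")
  }
  n <- length(tree$tip.label)
  if (n == 1L) return(stats::setNames(1, tree$tip.label))
  C <- ape::vcv(tree)
  ones <- rep(1, n)
  # pseudo-inverse via SVD; tolerant of singular covariances
  sv <- svd(C)
  pos <- sv$d > max(sv$d) * 1e-12
  if (!any(pos)) {
    w <- ones / n
  } else {
    Cinv1 <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% ones) / sv$d[pos])
    w <- as.numeric(Cinv1)
    if (all(abs(w) < 1e-300)) w <- ones / n
  }
  w <- w / sum(w)
  # ACL weights can go non-positive on pathological trees; clamp and
  # renormalise so downstream profiles stay well defined.
  if (any(w <= 0)) {
    w <- pmax(w, 1e-8)
    w <- w / sum(w)
  }
  stats::setNames(w, colnames(C))[tree$tip.label]
}

# Per-row weights: species weight split evenly across that species' genes,
# then shared by all rows (isoforms) of each gene.  Returns list with
# row_gene (gene key per row) and gene_weight (named by gene key).
.gene_weights <- function(baln, weights) {
  sp <- baln$meta$species
  if (!all(sp %in% names(weights))) {
    stop("alignment row with unknown species: ",
         paste(setdiff(sp, names(weights)), collapse = ", "))
  }
  gene_key <- paste(sp, baln$meta$gene, sep = "|")
  genes <- unique(gene_key)
  gene_sp <- sub("\\|.*$", "", genes)
  n_genes_per_sp <- table(gene_sp)
  gw <- weights[gene_sp] / as.numeric(n_genes_per_sp[gene_sp])
  names(gw) <- genes
  list(row_gene = gene_key, gene_weight = gw)
}

#' Weighted binary profile of an alignment
#'
#' Rows are grouped by gene; a species' weight is split evenly across its
#' genes.  Per column each gene group contributes its weight to the
#' non-gap count if at least one of its rows is non-gap, else to the gap
#' count.  Counts are initialised with a pseudocount for both symbols.
#'
#' @param baln A \code{binary_alignment}.
#' @param weights Species weights (see [gp_species_weights()]).
#' @param pseudocount Additive pseudocount per column per symbol,
#'   default 0.005.
#' @return A list of class \code{"binary_profile"} with \code{counts}
#'   (2 x L matrix, rows \code{gap}, \code{nongap}) and
#'   \code{pseudocount}.
#' @export
binary_profile <- function(baln, weights, pseudocount = 0.005) {
  gwl <- .gene_weights(baln, weights)
  L <- ncol(baln$mat)
  nongap <- rep(pseudocount, L)
  gap <- rep(pseudocount, L)
  for (g in unique(gwl$row_gene)) {
    rows <- baln$mat[gwl$row_gene == g, , drop = FALSE]
    any_nongap <- colSums(rows) > 0L
    w <- gwl$gene_weight[[g]]
    nongap <- nongap + w * any_nongap
    gap <- gap + w * !any_nongap
  }
  structure(list(counts = rbind(gap = gap, nongap = nongap),
                 pseudocount = pseudocount),
            class = "binary_profile")
}

#' Log-likelihood of a coded row under a binary profile
#'
#' @param profile A \code{binary_profile}.
#' @param coded_row Integer vector (1 = non-gap, 0 = gap) of profile width.
#' @return Sum over columns of \code{log(count(symbol) / total count)}.
#' @export
score_sequence <- function(profile, coded_row) {
  counts <- profile$counts
  stopifnot(length(coded_row) == ncol(counts))
  tot <- colSums(counts)
  sel <- ifelse(coded_row == 1L, counts["nongap", ], counts["gap", ])
  sum(log(sel / tot))
}

#' Select a representative accession per gene
#'
#' Per gene, the row maximising [score_sequence()] against the profile
#' built from the same alignment; ties break to the lexicographically
#' smallest accession.
#'
#' @param baln A \code{binary_alignment}.
#' @param profile A \code{binary_profile} built from \code{baln}.
#' @return Named character vector: gene key ("species|gene") to accession.
#' @export
select_representatives <- function(baln, profile) {
  gene_key <- paste(baln$meta$species, baln$meta$gene, sep = "|")
  scores <- apply(baln$mat, 1L, function(row) score_sequence(profile, row))
  out <- character(0)
  for (g in sort(unique(gene_key))) {
    rows <- which(gene_key == g)
    acc <- baln$meta$accession[rows]
    sc <- scores[rows]
    ord <- order(-sc, acc)
    out[[g]] <- acc[ord[1L]]
  }
  out
}

#' Weighted gap profile
#'
#' Per column, the sum of normalised weights of rows carrying a gap.
#' Intended for single-copy alignments with one row per species.
#'
#' @param baln A \code{binary_alignment} with one row per species.
#' @param weights Species weights summing to 1.
#' @return Numeric vector in [0, 1], one value per column.
#' @export
gap_profile <- function(baln, weights) {
  sp <- baln$meta$species
  if (!all(sp %in% names(weights))) stop("row with unknown species")
  if (any(duplicated(sp))) stop("gap_profile expects one row per species")
  w <- weights[sp]
  as.numeric(t(w) %*% (baln$mat == 0L))
}
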