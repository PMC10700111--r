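# Meta-alignment column sampling, reverse translation of protein
# alignments to nucleotide alignments, and majority / loose consensus
# trees from bipartition frequencies.

#' Sampling strategy for meta-alignments
#'
#' @param n_columns Number of columns per meta-alignment.
#' @param allow_invariant Keep columns whose non-gap symbols are all
#'   identical (all-gap columns count as invariant).
#' @param max_gap_fraction Maximum per-column gap fraction (0, 0.5 or 1).
#' @param seed Base seed.
#' @export
sampling_strategy <- function(n_columns = 10000L, allow_invariant = TRUE,
                              max_gap_fraction = 0.5, seed = 1L) {
  stopifnot(n_columns > 0L)
  list(n_columns = as.integer(n_columns),
       allow_invariant = allow_invariant,
       max_gap_fraction = max_gap_fraction,
       seed = as.integer(seed))
}

.aln_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

#' Sample a meta-alignment
#'
#' Columns are drawn uniformly with replacement from the global pool of
#' eligible columns across all input alignments.  A column is eligible if
#' its gap fraction is at most \code{max_gap_fraction} and, when invariant
#' columns are disallowed, its non-gap symbols are not all identical.
#'
#' @param alignments List of named character vectors, all over the same
#'   species set (names are species ids).
#' @param strategy A [sampling_strategy()].
#' @return Named character vector: the sampled alignment, rows ordered by
#'   species name.
#' @export
sample_meta_alignment <- function(alignments, strategy) {
  stopifnot(length(alignments) > 0L)
  species <- sort(names(alignments[[1L]]))
  pool <- list()
  for (aln in alignments) {
    if (!setequal(names(aln), species)) {
      stop("alignments must share one species set")
    }
    m <- .aln_char_matrix(aln)[species, , drop = FALSE]
    isgap <- m %in% GAP_CHARS
    dim(isgap) <- dim(m)
    gapfrac <- colMeans(isgap)
    ok <- gapfrac <= strategy$max_gap_fraction
    if (!strategy$allow_invariant) {
      inv <- vapply(seq_len(ncol(m)), function(j) {
        sym <- m[!isgap[, j], j]
        length(unique(sym)) <= 1L
      }, logical(1))
      ok <- ok & !inv
    }
    if (any(ok)) pool[[length(pool) + 1L]] <- m[, ok, drop = FALSE]
  }
  if (length(pool) == 0L) stop("no eligible columns under this strategy")
  pool <- do.call(cbind, pool)
  set.seed(strategy$seed)
  picked <- sample.int(ncol(pool), strategy$n_columns, replace = TRUE)
  out <- apply(pool[, picked, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(out, species)
}

# Standard genetic code, DNA codons.
.standard_code <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- unlist(strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), ""))
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aa, codons)
}

#' Translate a coding sequence
#'
#' @param cds DNA string (length divisible by 3).
#' @param codon_table Named character vector codon -> amino acid; default
#'   the standard code.
#' @return Amino-acid string ("X" for codons with ambiguity characters).
#' @export
translate_cds <- function(cds, codon_table = .standard_code()) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(toupper(cds), seq(1L, nchar(cds), 3L),
                      seq(3L, nchar(cds), 3L))
  aa <- codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse-translate a protein alignment to a nucleotide alignment
#'
#' Each residue column expands to its codon; gaps expand to three gaps.
#' The alignment is rejected (flagged, not an error) if the expected
#' translation of any coding sequence differs from its degapped protein
#' sequence, or if a CDS length is not divisible by 3.  A single trailing
#' stop codon on the CDS is tolerated and dropped.
#'
#' @param protein_aln Named character vector of aligned protein sequences.
#' @param cds_map Named character vector of coding sequences (same names).
#' @param codon_table Codon table (see [translate_cds()]).
#' @return List with \code{status} ("ok" or "rejected"), \code{alignment}
#'   (named character vector or NULL) and \code{reason}.
#' @export
reverse_translate <- function(protein_aln, cds_map,
                              codon_table = .standard_code()) {
  out <- character(length(protein_aln))
  names(out) <- names(protein_aln)
  for (id in names(protein_aln)) {
    if (!id %in% names(cds_map)) {
      return(list(status = "rejected", alignment = NULL,
                  reason = paste0("no CDS for ", id)))
    }
    cds <- toupper(cds_map[[id]])
    if (nchar(cds) %% 3L != 0L) {
      return(list(status = "rejected", alignment = NULL,
                  reason = paste0("CDS length not divisible by 3: ", id)))
    }
    prot <- degap(protein_aln[[id]])
    tr <- translate_cds(cds, codon_table)
    if (nchar(tr) == nchar(prot) + 1L && substring(tr, nchar(tr)) == "*") {
      tr <- substring(tr, 1L, nchar(tr) - 1L)
      cds <- substring(cds, 1L, nchar(cds) - 3L)
    }
    if (tr != prot) {
      return(list(status = "rejected", alignment = NULL,
                  reason = paste0("translation mismatch: ", id)))
    }
    chars <- strsplit(protein_aln[[id]], "")[[1L]]
    codons <- substring(cds, seq(1L, nchar(cds), 3L),
                        seq(3L, nchar(cds), 3L))
    pieces <- character(length(chars))
    ri <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] %in% GAP_CHARS) {
        pieces[i] <- "---"
      } else {
        ri <- ri + 1L
        pieces[i] <- codons[ri]
      }
    }
    out[[id]] <- paste(pieces, collapse = "")
  }
  list(status = "ok", alignment = out, reason = NA_character_)
}

# Canonical bipartition keys for one tree: for each internal edge, the
# tip-label set of the side NOT containing the reference tip, sorted and
# joined with "|".  Only non-trivial bipartitions (both sides >= 2 tips).
tree_bipartitions <- function(tree, ref) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    c <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    c <- po$edge[e, 2L]
    if (c <= ntip) next
    side <- below[[c]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# Two clades (both excluding the reference tip) are compatible iff nested
# or disjoint.
.clades_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

# Build a tree from a laminar family of clades over `tips` (all excluding
# `ref`), with per-clade support values; returns an ape phylo with node
# labels carrying supports.
.tree_from_clades <- function(tips, ref, clades, supports) {
  build <- function(members, idx) {
    # idx: indices of clades strictly inside `members`
    child_idx <- idx[order(-vapply(clades[idx], length, integer(1)))]
    used <- character(0)
    parts <- character(0)
    for (ci in child_idx) {
      cl <- clades[[ci]]
      if (length(intersect(cl, used))) next  # nested inside a sibling
      inner <- idx[vapply(idx, function(j) {
        j != ci && all(clades[[j]] %in% cl)
      }, logical(1))]
      parts <- c(parts, paste0(build(cl, inner),
                               sprintf("%.6g", supports[ci])))
      used <- c(used, cl)
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(parts, singles), collapse = ","), ")")
  }
  top_idx <- seq_along(clades)
  maximal <- top_idx[vapply(top_idx, function(i) {
    !any(vapply(top_idx, function(j) {
      j != i && all(clades[[i]] %in% clades[[j]]) &&
        length(clades[[j]]) > length(clades[[i]])
    }, logical(1)))
  }, logical(1))]
  used <- unique(unlist(clades[maximal]))
  parts <- vapply(maximal, function(ci) {
    inner <- top_idx[vapply(top_idx, function(j) {
      j != ci && all(clades[[j]] %in% clades[[ci]])
    }, logical(1))]
    paste0(build(clades[[ci]], inner), sprintf("%.6g", supports[ci]))
  }, character(1))
  singles <- setdiff(tips, used)
  nwk <- paste0("(", paste(c(ref, parts, singles), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Majority or loose consensus tree
#'
#' Counts non-trivial bipartitions across the input trees.  Majority mode
#' keeps bipartitions present in strictly more than 50% of trees.  Loose
#' mode greedily adds compatible bipartitions in descending frequency
#' (ties broken by the lexicographically smallest bipartition) until the
#' tree is fully resolved or the list is exhausted.  Node labels carry the
#' bipartition percentage.
#'
#' @param trees List of \code{phylo} objects (or a \code{multiPhylo})
#'   over identical tip sets.
#' @param mode \code{"majority"} or \code{"loose"}.
#' @return An ape \code{phylo}; node labels are support percentages.
#' @export
consensus_tree <- function(trees, mode = c("majority", "loose")) {
  mode <- match.arg(mode)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  tips <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, tips)) stop("tip sets differ across trees")
  }
  ref <- tips[1L]
  others <- setdiff(tips, ref)
  counts <- table(unlist(lapply(trees, tree_bipartitions, ref = ref)))
  n <- length(trees)
  freq <- as.numeric(counts) / n
  keys <- names(counts)
  ord <- order(-freq, keys)
  keys <- keys[ord]
  freq <- freq[ord]
  sel_keys <- character(0)
  sel_freq <- numeric(0)
  if (mode == "majority") {
    sel <- freq > 0.5
    sel_keys <- keys[sel]
    sel_freq <- freq[sel]
  } else {
    max_splits <- length(tips) - 3L
    clades_so_far <- list()
    for (i in seq_along(keys)) {
      if (length(sel_keys) >= max_splits) break
      cl <- strsplit(keys[i], "|", fixed = TRUE)[[1L]]
      if (all(vapply(clades_so_far, .clades_compatible, logical(1),
                     b = cl))) {
        clades_so_far <- c(clades_so_far, list(cl))
        sel_keys <- c(sel_keys, keys[i])
        sel_freq <- c(sel_freq, freq[i])
      }
    }
  }
  clades <- lapply(sel_keys, function(k) {
    strsplit(k, "|", fixed = TRUE)[[1L]]
  })
  .tree_from_clades(others, ref, clades, 100 * sel_freq)
}
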