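# Conversion of phylo-HMM posteriors into trim actions: seed-and-expand
# region definition on the posterior curve, per-sequence segment trimming
# of insertion (state 3) regions under a geometric cutoff, column trimming
# of skipped-exon (state 2) regions, and per-sequence missing-data
# segments.

#' Seed-and-expand region definition on a posterior curve
#'
#' Seeds are maximal runs of columns with posterior >= \code{high_cut}.
#' Each seed endpoint is expanded outward while the posterior stays >=
#' \code{low_cut} and the absolute forward-difference derivative stays >=
#' \code{d_out}, and inward (clamped at the seed) while the derivative
#' stays >= \code{d_in}.  Within each [outer, inner] window the boundary
#' is the step maximising |derivative| x |change in gap profile|; the
#' region starts after the maximising left step and ends at the
#' maximising right step.  Overlapping or adjacent expanded regions are
#' merged.
#'
#' @param prob Per-column posterior of the state of interest.
#' @param gap_profile Per-column weighted gap fraction (same length).
#' @param high_cut Seed threshold (inclusive).
#' @param low_cut Outward-expansion probability floor.
#' @param d_out Outward-expansion derivative floor.
#' @param d_in Inward-expansion derivative floor.
#' @return data.frame of regions with 1-based inclusive columns
#'   \code{start, end} and the seed interval \code{seed_start, seed_end}
#'   (seed columns of the merged region's first contributing seed).
#' @export
define_regions <- function(prob, gap_profile, high_cut = 0.75,
                           low_cut = 1e-3, d_out = 0.001, d_in = 0.001) {
  if (low_cut > high_cut) stop("low_cut must not exceed high_cut")
  n <- length(prob)
  stopifnot(length(gap_profile) == n)
  seeds <- runs_true(prob >= high_cut)
  if (nrow(seeds) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      seed_start = integer(0), seed_end = integer(0)))
  }
  # forward difference at step i: between columns i and i+1
  dprob <- if (n > 1L) diff(prob) else numeric(0)
  dgap <- if (n > 1L) abs(diff(gap_profile)) else numeric(0)
  product <- abs(dprob) * dgap
  left_bound <- integer(nrow(seeds))
  right_bound <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    s <- seeds$start[i]
    e <- seeds$end[i]
    # Left endpoint.  Steps are indexed by their left column: step j is the
    # transition between columns j and j+1; a left boundary at column c
    # corresponds to step c-1.
    outer <- s
    j <- s - 1L
    while (j >= 1L && prob[j] >= low_cut && abs(dprob[j]) >= d_out) {
      outer <- j
      j <- j - 1L
    }
    inner <- s  # inward expansion clamped at the seed's right end
    j <- s
    while (j < e && abs(dprob[j]) >= d_in) {
      inner <- j + 1L
      j <- j + 1L
    }
    steps <- (outer - 1L):(inner - 1L)
    steps <- steps[steps >= 1L & steps <= n - 1L]
    left_bound[i] <- if (length(steps)) {
      steps[which.max(product[steps])] + 1L
    } else s
    # Right endpoint: a right boundary at column c corresponds to step c.
    outer <- e
    j <- e
    while (j <= n - 1L && prob[j + 1L] >= low_cut &&
           abs(dprob[j]) >= d_out) {
      outer <- j + 1L
      j <- j + 1L
    }
    inner <- e  # inward expansion clamped at the seed's left end
    j <- e - 1L
    while (j >= s && abs(dprob[j]) >= d_in) {
      inner <- j
      j <- j - 1L
    }
    steps <- inner:outer
    steps <- steps[steps >= 1L & steps <= n - 1L]
    right_bound[i] <- if (length(steps)) {
      steps[which.max(product[steps])]
    } else e
    if (left_bound[i] > right_bound[i]) {
      left_bound[i] <- s
      right_bound[i] <- e
    }
  }
  iv <- data.frame(start = pmax(left_bound, 1L),
                   end = pmin(right_bound, n))
  merged <- merge_intervals(iv)
  # seed provenance: first and last seed overlapping each merged region
  merged$seed_start <- NA_integer_
  merged$seed_end <- NA_integer_
  for (i in seq_len(nrow(merged))) {
    ov <- which(seeds$end >= merged$start[i] &
                seeds$start <= merged$end[i])
    if (length(ov)) {
      merged$seed_start[i] <- seeds$start[ov[1L]]
      merged$seed_end[i] <- seeds$end[ov[length(ov)]]
    }
  }
  merged
}

#' Geometric trimming cutoff
#'
#' From a geometric model of the number of non-gap symbols in a poorly
#' supported region: with capped mean \code{mu} and significance level
#' \code{alpha}, \code{p = 1 / (mu + 1)} and
#' \code{k = log(alpha) / log(1 - p) - 1}.
#'
#' @param mu Capped weighted mean non-gap count, > 0.
#' @param alpha Significance level, default 0.01.
#' @return The real-valued cutoff k.
#' @export
geometric_cutoff <- function(mu, alpha = 0.01) {
  stopifnot(mu > 0, alpha > 0, alpha < 1)
  p <- 1 / (mu + 1)
  log(alpha) / log(1 - p) - 1
}

#' Per-sequence trimming of insertion (state 3) regions
#'
#' For each region the weighted mean non-gap count is computed (excluding
#' the \code{exclude_top} sequences with the most non-gap symbols, so long
#' poorly supported segments do not bias the estimate), capped at
#' \code{mu_cap}; any sequence whose non-gap count in the region equals or
#' exceeds the geometric cutoff is trimmed by replacing its non-gap
#' symbols with gaps.
#'
#' @param baln A \code{binary_alignment} (one row per species).
#' @param regions data.frame of regions from [define_regions()].
#' @param weights Normalised species weights.
#' @param alpha Significance level for the geometric cutoff.
#' @param mu_cap Cap on the mean non-gap count, default 2.
#' @param exclude_top Number of highest-count sequences excluded from the
#'   mean, default 5.
#' @return data.frame of segment trim actions with columns
#'   \code{kind, sequence, start, end}.
#' @export
trim_state3 <- function(baln, regions, weights, alpha = 0.01, mu_cap = 2,
                        exclude_top = 5L) {
  L <- ncol(baln$mat)
  acts <- list()
  w <- weights[baln$meta$species]
  for (i in seq_len(nrow(regions))) {
    if (regions$start[i] < 1L || regions$end[i] > L) {
      stop("region outside alignment")
    }
    cols <- regions$start[i]:regions$end[i]
    counts <- rowSums(baln$mat[, cols, drop = FALSE] == 1L)
    ord <- order(-counts)
    keep <- if (length(counts) > exclude_top) {
      ord[-(seq_len(exclude_top))]
    } else integer(0)
    mu <- if (length(keep) && sum(w[keep]) > 0) {
      sum(w[keep] * counts[keep]) / sum(w[keep])
    } else 0
    mu <- min(mu, mu_cap)
    # mu -> 0+ limit: p -> 1, so k -> -1 and any sequence with non-gap
    # symbols in the region qualifies
    k <- if (mu > 0) geometric_cutoff(mu, alpha) else -1
    trimmed <- which(counts >= k)
    for (r in trimmed) {
      if (counts[r] == 0L) next
      acts[[length(acts) + 1L]] <- data.frame(
        kind = "segment", sequence = rownames(baln$mat)[r],
        start = regions$start[i], end = regions$end[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(acts) == 0L) {
    return(data.frame(kind = character(0), sequence = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, acts)
}

#' Column trimming of skipped-exon (state 2) regions
#'
#' The state 2 posterior is added to a state 3 posterior that has been
#' zeroed inside already-trimmed state 3 regions (so regions intermediate
#' between the two states are still caught), regions are defined on the
#' combined curve with a high cutoff of 0.9, and every column of each
#' region becomes a column trim action.
#'
#' @param p2 Per-column posterior of state 2.
#' @param p3_masked State 3 posterior zeroed inside state 3 regions.
#' @param gap_profile Per-column weighted gap fraction.
#' @param high_cut Seed threshold, default 0.9.
#' @param low_cut,d_out,d_in Expansion thresholds (as in
#'   [define_regions()]).
#' @return data.frame of column trim actions with columns
#'   \code{kind, sequence (NA), start, end}.
#' @export
trim_state2 <- function(p2, p3_masked, gap_profile, high_cut = 0.9,
                        low_cut = 1e-3, d_out = 0.001, d_in = 0.001) {
  regions <- define_regions(p2 + p3_masked, gap_profile, high_cut,
                            low_cut, d_out, d_in)
  if (nrow(regions) == 0L) {
    return(data.frame(kind = character(0), sequence = character(0),
                      start = integer(0), end = integer(0)))
  }
  data.frame(kind = "column", sequence = NA_character_,
             start = regions$start, end = regions$end,
             stringsAsFactors = FALSE)
}

#' Missing-data segments for one sequence
#'
#' Seeds are runs of positions with missing-state posterior >=
#' \code{seed_cut}; each seed expands outward position by position,
#' stopping at the first non-gap symbol or as soon as the posterior drops
#' below \code{stop_cut}.  Overlapping segments are merged.
#'
#' @param post Per-position posterior of the missing state.
#' @param coded_row Integer vector (0 = gap, 1 = non-gap) for the
#'   sequence.
#' @param seed_cut Seed threshold, default 0.75.
#' @param stop_cut Expansion posterior floor, default 0.05.
#' @return data.frame of missing segments with 1-based inclusive
#'   \code{start, end}.
#' @export
call_missing <- function(post, coded_row, seed_cut = 0.75,
                         stop_cut = 0.05) {
  n <- length(post)
  stopifnot(length(coded_row) == n)
  # seeds are restricted to gap positions: a residue that is present can
  # never itself be missing, so segments are always gap runs
  seeds <- runs_true(post >= seed_cut & coded_row == 0L)
  if (nrow(seeds) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  for (i in seq_len(nrow(seeds))) {
    j <- seeds$start[i] - 1L
    while (j >= 1L && coded_row[j] == 0L && post[j] >= stop_cut) {
      seeds$start[i] <- j
      j <- j - 1L
    }
    j <- seeds$end[i] + 1L
    while (j <= n && coded_row[j] == 0L && post[j] >= stop_cut) {
      seeds$end[i] <- j
      j <- j + 1L
    }
  }
  merge_intervals(seeds)
}

#' Serialize missing segments as slice lists
#'
#' Formats segments as 0-based half-open slices
#' \code{"start0-stop0,start1-stop1,..."}; an empty data.frame yields an
#' empty string.
#'
#' @param segments data.frame with 1-based inclusive \code{start, end}.
#' @return A single string.
#' @export
format_slices <- function(segments) {
  if (nrow(segments) == 0L) return("")
  paste(sprintf("%d-%d", segments$start - 1L, segments$end),
        collapse = ",")
}

#' Apply trim actions to an alignment
#'
#' Segment trims replace the sequence's non-gap symbols with gaps inside
#' the region (alignment width unchanged); column trims delete the
#' columns (row count unchanged).  Segment trims are applied first.
#'
#' @param aln Named character vector of aligned sequences.
#' @param actions data.frame of trim actions (see [trim_state3()] and
#'   [trim_state2()]).
#' @return The trimmed alignment.
#' @export
apply_trims <- function(aln, actions) {
  chars <- strsplit(aln, "")
  seg <- actions[actions$kind == "segment", , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    r <- seg$sequence[i]
    cols <- seg$start[i]:seg$end[i]
    chars[[r]][cols] <- "-"
  }
  col <- actions[actions$kind == "column", , drop = FALSE]
  if (nrow(col)) {
    drop <- unique(unlist(lapply(seq_len(nrow(col)), function(i) {
      col$start[i]:col$end[i]
    })))
    chars <- lapply(chars, function(ch) ch[-drop])
  }
  out <- vapply(chars, paste, character(1), collapse = "")
  names(out) <- names(aln)
  out
}

#' Full curation pass over one single-copy alignment
#'
#' Runs the insertion phylo-HMM, zeroes the state 3 posterior over highly
#' conserved columns (gap profile <= \code{conserved_gap}), defines and
#' trims state 3 regions per sequence, then defines and trims state 2
#' regions per column, and returns all actions plus the posterior matrix.
#'
#' @param aln Named character vector (single-copy: names are accessions).
#' @param meta Row metadata with species per accession.
#' @param spec Insertion-model \code{hmm_spec} whose states include
#'   \code{"2"} and \code{"3"}.
#' @param tree Rooted \code{phylo} over the species.
#' @param weights Species weights.
#' @param conserved_gap Gap-profile ceiling for zeroing state 3, default
#'   0.1.
#' @return List with \code{actions}, \code{posterior},
#'   \code{state3_regions} and \code{state2_regions}.
#' @export
curate_alignment <- function(aln, meta, spec, tree, weights,
                             conserved_gap = 0.1) {
  baln <- code_binary(aln, meta)
  columns <- baln$mat
  rownames(columns) <- baln$meta$species
  gp <- gap_profile(baln, weights)
  fb <- decode_insertion(spec, tree, columns)
  p2 <- fb$posterior[, "2"]
  p3 <- fb$posterior[, "3"]
  p3_broken <- ifelse(gp <= conserved_gap, 0, p3)
  regions3 <- define_regions(p3_broken, gp, high_cut = 0.75,
                             low_cut = 1e-3, d_out = 0.001, d_in = 0.001)
  acts3 <- trim_state3(baln, regions3, weights)
  p3_masked <- p3
  for (i in seq_len(nrow(regions3))) {
    p3_masked[regions3$start[i]:regions3$end[i]] <- 0
  }
  acts2 <- trim_state2(p2, p3_masked, gp)
  actions <- rbind(acts3, acts2)
  list(actions = actions, posterior = fb$posterior,
       state3_regions = regions3, state2_regions = acts2)
}
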