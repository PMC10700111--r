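# Internal helpers shared across modules.

# Runs of TRUE in a logical vector, as a data.frame of 1-based inclusive
# [start, end] column indices.
runs_true <- function(x) {
  stopifnot(is.logical(x))
  if (length(x) == 0L || !any(x)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Merge 1-based inclusive intervals that overlap or touch.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1L]
  out_e <- iv$end[1L]
  res_s <- integer(0)
  res_e <- integer(0)
  if (nrow(iv) > 1L) {
    for (i in 2L:nrow(iv)) {
      if (iv$start[i] <= out_e + 1L) {
        out_e <- max(out_e, iv$end[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- iv$start[i]; out_e <- iv$end[i]
      }
    }
  }
  res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
  data.frame(start = res_s, end = res_e)
}

# Length of the union of half-open intervals given as a 2-column matrix
# [start, stop).
interval_union_length <- function(starts, stops) {
  if (length(starts) == 0L) return(0)
  o <- order(starts, stops)
  starts <- starts[o]; stops <- stops[o]
  total <- 0
  cur_s <- starts[1L]; cur_e <- stops[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, stops[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- stops[i]
    }
  }
  total + (cur_e - cur_s)
}

# Overlap length of two half-open intervals.
overlap_len <- function(a_start, a_stop, b_start, b_stop) {
  max(0, min(a_stop, b_stop) - max(a_start, b_start))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
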