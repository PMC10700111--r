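# Unit tests for region definition, the geometric cutoff, state 2/3
# trimming and missing-segment calls.

test_that("define_regions places boundaries at coincident steps", {
  n <- 20
  prob <- c(rep(0, 9), rep(1, 11))
  gp <- c(rep(0.1, 9), rep(0.9, 11))
  r <- define_regions(prob, gp, high_cut = 0.75, low_cut = 1e-3,
                      d_out = 0.001, d_in = 0.001)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 10L)
  expect_equal(r$end, 20L)  # clamped at the alignment edge
  # no column reaches the high cutoff: no regions
  expect_equal(nrow(define_regions(rep(0.5, 10), rep(0.5, 10))), 0L)
  # cutoff ordering is validated
  expect_error(define_regions(prob, gp, high_cut = 0.1, low_cut = 0.5),
               "low_cut")
  # seed touching both edges clamps to the whole alignment
  r2 <- define_regions(rep(1, 8), rep(0.5, 8))
  expect_equal(c(r2$start, r2$end), c(1L, 8L))
})

test_that("define_regions merges overlapping expanded regions", {
  prob <- c(0, 0.8, 0.8, 0.4, 0.8, 0.8, 0)
  gp <- c(0.1, 0.9, 0.9, 0.5, 0.9, 0.9, 0.1)
  r <- define_regions(prob, gp, high_cut = 0.75, low_cut = 0.3,
                      d_out = 0.001, d_in = 0.001)
  expect_equal(nrow(r), 1L)
})

test_that("geometric_cutoff evaluates the printed formula", {
  # independent evaluation: p = 1/(mu+1), k = log(alpha)/log(1-p) - 1
  expect_equal(geometric_cutoff(2, 0.01),
               log(0.01) / log(1 - 1 / 3) - 1, tolerance = 1e-12)
  expect_equal(geometric_cutoff(2, 0.01), 10.3578, tolerance = 1e-4)
  expect_equal(geometric_cutoff(1, 0.01),
               log(0.01) / log(0.5) - 1, tolerance = 1e-12)
  expect_equal(geometric_cutoff(1, 0.01), 5.6439, tolerance = 1e-4)
  # strictly decreasing in mu for fixed alpha
  mus <- seq(0.1, 5, by = 0.1)
  ks <- vapply(mus, geometric_cutoff, numeric(1))
  expect_true(all(diff(ks) > 0))  # larger mean, larger cutoff
  expect_error(geometric_cutoff(0, 0.01))
})

curation_fixture <- function(counts, width = 20L) {
  # 8 single-species rows; row i has counts[i] non-gap symbols packed
  # from the left of the region
  n <- length(counts)
  mat <- matrix(0L, n, width)
  for (i in seq_len(n)) if (counts[i] > 0) mat[i, seq_len(counts[i])] <- 1L
  rn <- sprintf("r%02d", seq_len(n))
  rownames(mat) <- rn
  meta <- data.frame(accession = rn, species = sprintf("s%02d", seq_len(n)),
                     gene = rn, stringsAsFactors = FALSE)
  structure(list(mat = mat, meta = meta), class = "binary_alignment")
}

test_that("trim_state3 trims sequences at or above the geometric cutoff", {
  # top-5 counts are excluded from the mean; remaining rows average mu = 2
  counts <- c(11L, 10L, 9L, 8L, 7L, 2L, 2L, 2L)
  baln <- curation_fixture(counts)
  w <- setNames(rep(1 / 8, 8), baln$meta$species)
  regions <- data.frame(start = 1L, end = 20L, seed_start = 1L,
                        seed_end = 20L)
  acts <- trim_state3(baln, regions, w)
  # k = 10.3578: the count-11 row is trimmed, the count-10 row is not
  expect_equal(acts$sequence, "r01")
  expect_equal(acts$kind, "segment")
  # all-gap region produces no actions
  baln0 <- curation_fixture(rep(0L, 8))
  expect_equal(nrow(trim_state3(baln0, regions, w)), 0L)
  # region outside the alignment errors
  bad <- data.frame(start = 1L, end = 99L, seed_start = 1L, seed_end = 2L)
  expect_error(trim_state3(baln, bad, w), "outside")
})

test_that("trim_state3 in the mu = 0 limit trims any non-gap carrier", {
  counts <- c(30L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  baln <- curation_fixture(counts, width = 30L)
  w <- setNames(rep(1 / 8, 8), baln$meta$species)
  regions <- data.frame(start = 1L, end = 30L, seed_start = 1L,
                        seed_end = 30L)
  acts <- trim_state3(baln, regions, w)
  expect_equal(acts$sequence, "r01")
})

test_that("trim_state3 is idempotent on insertion-like regions", {
  # one long carrier against background zeros: the configuration the
  # state 3 trimmer targets in practice.  (For arbitrary count smears the
  # second pass can re-trim because the excluded top-5 set changes; see
  # the methods vignette.)
  counts <- c(18L, 0L, 0L, 1L, 0L, 2L, 0L, 0L)
  baln <- curation_fixture(counts)
  w <- setNames(rep(1 / 8, 8), baln$meta$species)
  regions <- data.frame(start = 1L, end = 20L, seed_start = 1L,
                        seed_end = 20L)
  acts <- trim_state3(baln, regions, w)
  aln <- apply(baln$mat, 1, function(r) {
    paste(ifelse(r == 1L, "A", "-"), collapse = "")
  })
  trimmed <- apply_trims(aln, acts)
  baln2 <- code_binary(trimmed, baln$meta)
  acts2 <- trim_state3(baln2, regions, w)
  expect_equal(nrow(acts2), 0L)
})

test_that("trim_state2 trims whole columns of combined-probability regions", {
  n <- 20
  gp <- rep(0.5, n)
  # nothing above 0.9: no trims
  expect_equal(nrow(trim_state2(rep(0.5, n), rep(0.3, n), gp)), 0L)
  # region spanning columns 5..12
  p2 <- rep(0, n); p2[5:12] <- 0.95
  gp2 <- rep(0.1, n); gp2[5:12] <- 0.9
  acts <- trim_state2(p2, rep(0, n), gp2)
  expect_equal(acts$kind, "column")
  expect_equal(sum(acts$end - acts$start + 1), 8)
  # intermediate region: p2 + masked p3 >= 0.9 combined
  p2b <- rep(0, n); p2b[5:12] <- 0.5
  p3b <- rep(0, n); p3b[5:12] <- 0.45
  acts2 <- trim_state2(p2b, p3b, gp2)
  expect_equal(nrow(acts2), 1L)
})

test_that("call_missing expands seeds across gap runs only", {
  # all-zero posterior: nothing
  expect_equal(nrow(call_missing(rep(0, 10), rep(1L, 10))), 0L)
  # seed inside a gap run flanked by residues spans exactly the run
  row <- c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L)
  post <- c(0, 0, 0.2, 0.9, 0.9, 0.2, 0, 0)
  seg <- call_missing(post, row)
  expect_equal(c(seg$start, seg$end), c(3L, 6L))
  # expansion also stops when the posterior drops below 0.05
  post2 <- c(0, 0, 0.01, 0.9, 0.9, 0.2, 0, 0)
  seg2 <- call_missing(post2, row)
  expect_equal(c(seg2$start, seg2$end), c(4L, 6L))
  # two seeds merging after expansion give one segment
  row3 <- rep(0L, 10)
  post3 <- c(0.9, 0.9, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.9, 0.9)
  seg3 <- call_missing(post3, row3)
  expect_equal(nrow(seg3), 1L)
  expect_equal(c(seg3$start, seg3$end), c(1L, 10L))
})

test_that("format_slices serialises 0-based half-open slices", {
  segs <- data.frame(start = c(3L, 10L), end = c(6L, 12L))
  expect_equal(format_slices(segs), "2-6,9-12")
  expect_equal(format_slices(segs[0, ]), "")
})

test_that("apply_trims preserves width for segments and rows for columns", {
  aln <- c(r1 = "AAAAAAAA", r2 = "AAAAAAAA")
  seg <- data.frame(kind = "segment", sequence = "r1", start = 3L,
                    end = 5L, stringsAsFactors = FALSE)
  out <- apply_trims(aln, seg)
  expect_equal(nchar(out), nchar(aln))
  expect_equal(out[["r1"]], "AA---AAA")
  expect_equal(out[["r2"]], aln[["r2"]])
  col <- data.frame(kind = "column", sequence = NA_character_,
                    start = 2L, end = 3L, stringsAsFactors = FALSE)
  out2 <- apply_trims(aln, col)
  expect_equal(length(out2), 2L)
  expect_equal(unname(nchar(out2)), c(6L, 6L))
})
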