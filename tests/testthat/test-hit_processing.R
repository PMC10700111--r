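# Unit tests for HSP parsing, merging, best-hit selection and filtering.

mk_records <- function(acc, gene, seqs, species = "s1") {
  data.frame(accession = acc, gene = gene, species = species,
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("deduplicate_proteins keeps first accession per (gene, sequence)", {
  r <- mk_records(c("P1", "P2", "P3"), "G", c("MAD", "MAD", "MADE"))
  expect_equal(deduplicate_proteins(r)$accession, c("P1", "P3"))
  # single record is identity
  r1 <- mk_records("P1", "G", "MAD")
  expect_equal(deduplicate_proteins(r1), r1)
  # identical sequence under two genes: both retained (rule is per gene)
  r2 <- mk_records(c("P1", "P2"), c("G1", "G2"), c("MAD", "MAD"))
  expect_equal(deduplicate_proteins(r2)$accession, c("P1", "P2"))
  # same sequence+gene in two species: both retained
  r3 <- rbind(mk_records("P1", "G", "MAD", "s1"),
              mk_records("P1b", "G", "MAD", "s2"))
  expect_equal(nrow(deduplicate_proteins(r3)), 2L)
  # duplicate accession within a species rejected
  r4 <- mk_records(c("P1", "P1"), "G", c("MAD", "MAE"))
  expect_error(deduplicate_proteins(r4), "duplicate accession")
})

test_that("filter_by_evalue applies an inclusive threshold", {
  h <- data.frame(evalue = c(1e-12, 1e-5, 1e-10))
  expect_equal(filter_by_evalue(h)$evalue, c(1e-12, 1e-10))
  expect_equal(nrow(filter_by_evalue(h[0, , drop = FALSE])), 0L)
})

mk_hsp <- function(sseqid, bitscore, sgene, qstart = 0, qend = 10,
                   qlen = 10) {
  data.frame(qseqid = "q", sseqid = sseqid, bitscore = bitscore,
             evalue = 1e-20, qstart = qstart, qend = qend,
             sstart = qstart, send = qend, qlen = qlen, slen = qlen,
             sgene = sgene, stringsAsFactors = FALSE)
}

test_that("extract_best_gene_hsps emits ranked groups until the gene changes", {
  h <- rbind(mk_hsp("T1", 100, "gA"), mk_hsp("T2", 90, "gA"),
             mk_hsp("T3", 80, "gB"))
  expect_setequal(unique(extract_best_gene_hsps(h)$sseqid), c("T1", "T2"))
  # single group passes through
  expect_equal(extract_best_gene_hsps(mk_hsp("T1", 50, "gA"))$sseqid, "T1")
  # tie at the top: both tied genes admit later groups of either gene
  h2 <- rbind(mk_hsp("T1", 100, "gA"), mk_hsp("T2", 100, "gB"),
              mk_hsp("T3", 95, "gA"))
  expect_setequal(unique(extract_best_gene_hsps(h2)$sseqid),
                  c("T1", "T2", "T3"))
  # iteration stops at the first group outside the tied top genes
  h3 <- rbind(h2, mk_hsp("T4", 90, "gC"), mk_hsp("T5", 85, "gA"))
  expect_setequal(unique(extract_best_gene_hsps(h3)$sseqid),
                  c("T1", "T2", "T3"))
})

test_that("extract_best_gene_hsps is invariant to input row order", {
  set.seed(41)
  h <- rbind(mk_hsp("T1", 100, "gA"), mk_hsp("T1", 40, "gA"),
             mk_hsp("T2", 90, "gA"), mk_hsp("T3", 80, "gB"),
             mk_hsp("T4", 70, "gB"))
  ref <- sort(extract_best_gene_hsps(h)$sseqid)
  for (i in 1:10) {
    perm <- h[sample.int(nrow(h)), , drop = FALSE]
    expect_equal(sort(extract_best_gene_hsps(perm)$sseqid), ref)
  }
})

mk_pair_hsps <- function(scores, qstarts, qends, qlen = 100) {
  data.frame(qseqid = "q", sseqid = "t", bitscore = scores,
             evalue = 1e-20, qstart = qstarts, qend = qends,
             sstart = qstarts, send = qends, qlen = qlen, slen = qlen,
             stringsAsFactors = FALSE)
}

test_that("merge_hsps marks disjoint and compatible sets as specified", {
  # A(100, [0,50)), B(60, [40,90)), C(50, [50,100))
  hit <- merge_hsps(mk_pair_hsps(c(100, 60, 50), c(0, 40, 50),
                                 c(50, 90, 100)))
  dj <- hit$hsps[hit$hsps$disjoint, ]
  cp <- hit$hsps[hit$hsps$compatible, ]
  expect_setequal(dj$bitscore, c(100, 50))
  expect_setequal(cp$bitscore, c(100, 50))  # B overlaps C by 40 > 25
  expect_equal(hit$disjoint_score, 150)
  expect_equal(hit$query_coverage, 1.0)
  # single HSP: disjoint and compatible
  h1 <- merge_hsps(mk_pair_hsps(70, 10, 60))
  expect_true(h1$hsps$disjoint && h1$hsps$compatible)
  expect_equal(h1$disjoint_score, 70)
  # identical intervals: second neither disjoint nor compatible
  # (overlap = 100% of either)
  h2 <- merge_hsps(mk_pair_hsps(c(10, 9), c(0, 0), c(50, 50)))
  expect_equal(sum(h2$hsps$disjoint), 1L)
  expect_equal(sum(h2$hsps$compatible), 1L)
  # empty input yields no hit
  expect_null(merge_hsps(mk_pair_hsps(70, 10, 60)[0, , drop = FALSE]))
})

test_that("merge_hsps compatible admits overlap at exactly 50% of either", {
  # intervals [0,40) and [20,60): overlap 20 = 0.5 * 40 for both
  h <- merge_hsps(mk_pair_hsps(c(50, 40), c(0, 20), c(40, 60)))
  expect_equal(sum(h$hsps$compatible), 2L)
  # overlap 21 > 20 fails
  h2 <- merge_hsps(mk_pair_hsps(c(50, 40), c(0, 19), c(40, 59)))
  expect_equal(sum(h2$hsps$compatible), 1L)
})

test_that("disjoint sets are non-overlapping and greedy score <= optimum", {
  set.seed(99)
  for (rep in 1:60) {
    h <- random_hsps(sample(1:12, 1L))
    hit <- merge_hsps(h)
    dj <- hit$hsps[hit$hsps$disjoint, , drop = FALSE]
    if (nrow(dj) > 1L) {
      for (i in 1:(nrow(dj) - 1L)) for (j in (i + 1L):nrow(dj)) {
        expect_equal(orthotrim:::overlap_len(dj$qstart[i], dj$qend[i],
                                             dj$qstart[j], dj$qend[j]), 0)
      }
    }
    opt <- oracle_wis(h$qstart, h$qend, h$bitscore)
    expect_lte(hit$disjoint_score, opt + 1e-9)
  }
})

test_that("select_best_hit maximises disjoint score with lexicographic ties", {
  mk <- function(t, score) {
    merge_hsps(data.frame(qseqid = "q", sseqid = t, bitscore = score,
                          evalue = 1e-20, qstart = 0, qend = 50,
                          sstart = 0, send = 50, qlen = 100, slen = 100))
  }
  expect_equal(select_best_hit(list(mk("T1", 150), mk("T2", 140)))$target,
               "T1")
  expect_equal(select_best_hit(list(mk("T9", 80)))$target, "T9")
  expect_equal(select_best_hit(list(mk("T1", 150), mk("T0", 150)))$target,
               "T0")
  expect_null(select_best_hit(list()))
})

test_that("apply_hit_filters enforces coverage and reciprocity", {
  mk <- function(q, t, score, cov_end) {
    merge_hsps(data.frame(qseqid = q, sseqid = t, bitscore = score,
                          evalue = 1e-20, qstart = 0, qend = cov_end,
                          sstart = 0, send = cov_end, qlen = 100,
                          slen = 100))
  }
  # coverage boundary: 0.49 dropped, 0.50 kept
  e1 <- apply_hit_filters(list(mk("a", "b", 10, 49), mk("b", "a", 10, 49)))
  expect_equal(nrow(e1), 0L)
  e2 <- apply_hit_filters(list(mk("a", "b", 10, 50), mk("b", "a", 12, 50)))
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$score, 12)  # symmetrised as the max of both directions
  # reciprocity: best hit of b is u, so no a-b edge
  e3 <- apply_hit_filters(list(mk("a", "b", 10, 80), mk("b", "u", 11, 80),
                               mk("u", "b", 11, 80)))
  expect_equal(nrow(e3), 1L)
  expect_equal(c(e3$a, e3$b), c("b", "u"))
})

test_that("detect_paralogs uses a strict score comparison", {
  self <- function(score) {
    rbind(
      data.frame(qseqid = "p1", sseqid = "p2", bitscore = score,
                 evalue = 1e-30, qstart = 0, qend = 100, sstart = 0,
                 send = 100, qlen = 100, slen = 100,
                 qgene = "g1", sgene = "g2", qspecies = "s",
                 sspecies = "s", stringsAsFactors = FALSE),
      data.frame(qseqid = "p2", sseqid = "p1", bitscore = score,
                 evalue = 1e-30, qstart = 0, qend = 100, sstart = 0,
                 send = 100, qlen = 100, slen = 100,
                 qgene = "g2", sgene = "g1", qspecies = "s",
                 sspecies = "s", stringsAsFactors = FALSE))
  }
  imax <- c(p1 = 180, p2 = 100)
  expect_equal(nrow(detect_paralogs(self(200), imax)), 1L)
  # exactly equal is not an excess
  expect_equal(nrow(detect_paralogs(self(180), imax)), 0L)
  # no inter-genome hits: -Inf comparison admits the pair
  expect_equal(nrow(detect_paralogs(self(5), c(other = 1))), 1L)
})

test_that("BLAST tabular parsing converts to 0-based half-open intervals", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# comment line",
               "q1\tt1\t55.3\t1e-20\t1\t50\t3\t52\t100\t120"), tmp)
  h <- read_blast_tab(tmp)
  expect_equal(h$qstart, 0)
  expect_equal(h$qend, 50)
  expect_equal(h$sstart, 2)
  expect_equal(h$send, 52)
})
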