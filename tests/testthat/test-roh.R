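test_that("window scan flags homozygous stretches and rejects het-dense ones", {
  p <- roh_params()
  expect_true(all(roh_window_scan(rep(0L, 100), p)))
  expect_true(all(roh_window_scan(rep(2L, 100), p)))
  expect_false(any(roh_window_scan(rep(c(1L, 0L), 50), p)))
  # fewer SNPs than one window: nothing is eligible
  expect_false(any(roh_window_scan(rep(0L, 19), p)))
})

test_that("window scan equals exhaustive window enumeration", {
  p <- roh_params()
  g <- c(rep(0L, 60), 1L, rep(2L, 60))
  expect_identical(roh_window_scan(g, p), bf_window_scan(g, p))
  set.seed(801)
  for (rep in 1:20) {
    n <- sample(20:500, 1)
    g <- sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.45, .1, .4, .05))
    pars <- roh_params(window_snps = sample(c(5L, 10L, 20L), 1),
                       max_het_per_window = sample(0:2, 1),
                       max_missing_per_window = sample(0:2, 1),
                       window_hit_threshold = sample(c(0.01, 0.05, 0.5), 1))
    expect_identical(roh_window_scan(g, pars), bf_window_scan(g, pars))
  }
})

test_that("segment calling respects length, SNP count, gap and density rules", {
  p <- roh_params()
  # planted 1.2-Mb homozygous tract flanked by heterozygous sites
  pos <- c(seq(1e5, 9e5, by = 25e3),                  # het flank
           seq(1e6, 2.2e6, by = 25e3),                # hom tract, 49 SNPs
           seq(2.3e6, 3.1e6, by = 25e3))              # het flank
  g <- c(rep(1L, 33), rep(0L, 49), rep(1L, 33))
  el <- roh_window_scan(g, p)
  segs <- roh_call_segments(pos, g, el, p)
  expect_equal(nrow(segs), 1L)
  expect_lte(abs(segs$start_bp - 1e6), 25e3)
  expect_lte(abs(segs$end_bp - 2.2e6), 25e3)
  # a 0.8-Mb tract fails the 1000-kb minimum
  pos2 <- c(seq(1e5, 9e5, by = 25e3), seq(1e6, 1.8e6, by = 25e3),
            seq(1.9e6, 2.7e6, by = 25e3))
  g2 <- c(rep(1L, 33), rep(0L, 33), rep(1L, 33))
  segs2 <- roh_call_segments(pos2, g2, roh_window_scan(g2, p), p)
  expect_equal(nrow(segs2), 0L)
  # fully heterozygous individual yields nothing
  g3 <- rep(1L, 100)
  expect_equal(nrow(roh_call_segments(seq_len(100) * 25e3, g3,
                                      roh_window_scan(g3, p), p)), 0L)
  # a gap above max_gap_kb splits a run (both halves then fail min_kb)
  pos4 <- c(seq(1e6, 1.75e6, by = 25e3), seq(3e6, 3.75e6, by = 25e3))
  g4 <- rep(0L, length(pos4))
  segs4 <- roh_call_segments(pos4, g4, roh_window_scan(g4, p), p)
  expect_equal(nrow(segs4), 0L)
  # the same span without the gap passes
  pos5 <- seq(1e6, 2.75e6, by = 25e3)
  g5 <- rep(0L, length(pos5))
  expect_equal(nrow(roh_call_segments(pos5, g5, roh_window_scan(g5, p), p)),
               1L)
  # sparser than density_kb_per_snp is rejected
  p_dense <- roh_params(min_snps_in_run = 5L, window_snps = 5L,
                        density_kb_per_snp = 50)
  pos6 <- seq(1e6, 2.5e6, by = 75e3)   # 75 kb/SNP
  g6 <- rep(0L, length(pos6))
  expect_equal(nrow(roh_call_segments(pos6, g6,
                                      roh_window_scan(g6, p_dense),
                                      p_dense)), 0L)
})

test_that("ROH summary statistics follow their definitions", {
  segs <- data.frame(sample = "s1", chrom = "chr1",
                     start_bp = c(1, 1), end_bp = c(2, 2),
                     n_snps = c(30L, 60L), length_kb = c(1000, 3000))
  genome <- genome_model(data.frame(chrom = "chr1", length = 1e8,
                                    is_autosome = TRUE))
  s <- summarize_roh(segs, genome)
  expect_equal(s$sroh_kb, 4000)
  expect_equal(s$nroh, 2L)
  expect_equal(s$lroh_kb, 2000)
  expect_equal(s$f_roh, 0.04)
  empty <- summarize_roh(segs[0, ], genome, samples = "s1")
  expect_equal(empty$sroh_kb, 0)
  expect_equal(empty$f_roh, 0)
  expect_true(is.na(empty$lroh_kb))
})

test_that("raising the minimum length never increases NROH or SROH", {
  set.seed(802)
  genome <- simple_genome(1e7)
  for (rep in 1:5) {
    n <- 400
    pos <- sort(sample(1e7, n))
    g <- ifelse(runif(n) < 0.2, 1L, 0L)
    run <- sample(n - 80, 1)
    g[run:(run + 79)] <- 0L
    vt <- make_vt(matrix(g, n, 1), pos = pos)
    prev <- NULL
    for (mk in c(200, 500, 1000, 2000)) {
      p <- roh_params(min_kb = mk, min_snps_in_run = 10L,
                      window_snps = 10L)
      s <- summarize_roh(detect_roh(vt, p), genome, samples = "S01")
      if (!is.null(prev)) {
        expect_lte(s$nroh, prev$nroh)
        expect_lte(s$sroh_kb, prev$sroh_kb)
      }
      prev <- s
    }
  }
})

test_that("planted autozygous tracts are recovered on the simulated cohort", {
  co <- cohort_default()
  segs <- detect_roh(co$auto_ingroup)
  tracts <- co$truth$roh_tracts
  # recall: every planted tract matched by a called segment with
  # reciprocal overlap >= 0.95; precision: every called segment matches a
  # planted tract
  overlap <- function(a_start, a_end, b_start, b_end) {
    inter <- max(0, min(a_end, b_end) - max(a_start, b_start) + 1)
    inter / max(a_end - a_start + 1, b_end - b_start + 1)
  }
  recall_hits <- vapply(seq_len(nrow(tracts)), function(i) {
    cand <- segs[segs$sample == tracts$sample[i] &
                   segs$chrom == tracts$chrom[i], , drop = FALSE]
    any(vapply(seq_len(nrow(cand)), function(j)
      overlap(cand$start_bp[j], cand$end_bp[j],
              tracts$start[i], tracts$end[i]) >= 0.95, TRUE))
  }, TRUE)
  expect_true(all(recall_hits))
  precision_hits <- vapply(seq_len(nrow(segs)), function(j) {
    cand <- tracts[tracts$sample == segs$sample[j] &
                     tracts$chrom == segs$chrom[j], , drop = FALSE]
    any(vapply(seq_len(nrow(cand)), function(i)
      overlap(segs$start_bp[j], segs$end_bp[j],
              cand$start[i], cand$end[i]) >= 0.95, TRUE))
  }, TRUE)
  expect_true(all(precision_hits))
  # the planted 10%-autozygous genome lands within 0.02 of F_ROH = 0.10
  summ <- summarize_roh(segs, co$genome, samples = co$ingroup)
  f1 <- summ$f_roh[summ$sample == "pop1_01"]
  expect_lt(abs(f1 - 0.10), 0.02)
  # samples without planted tracts show no ROH at this diversity
  none <- setdiff(co$ingroup, tracts$sample)
  expect_true(all(summ$f_roh[summ$sample %in% none] == 0))
})
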