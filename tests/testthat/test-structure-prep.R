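test_that("genotype r2 matches an independent covariance-ratio computation", {
  set.seed(701)
  g1 <- sample(0:2, 20, TRUE)
  expect_equal(genotype_r2(g1, g1), 1)
  expect_equal(genotype_r2(g1, 2L - g1), 1)   # sign-invariance
  for (rep in 1:10) {
    a <- sample(0:2, 20, TRUE)
    b <- sample(0:2, 20, TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    cov_ab <- mean(a * b) - mean(a) * mean(b)
    var_a <- mean(a^2) - mean(a)^2
    var_b <- mean(b^2) - mean(b)^2
    expect_equal(genotype_r2(a, b), cov_ab^2 / (var_a * var_b),
                 tolerance = 1e-12)
  }
  expect_equal(genotype_r2(rep(1L, 10), sample(0:2, 10, TRUE)), 0)
  expect_error(genotype_r2(1:4, 1:5), "length")
})

test_that("exact HWE test agrees with full enumeration", {
  # monomorphic: a single possible table
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  # (1,0,1): two alleles of each type in two diploids; het counts {0, 2}
  # P(het=0) = 1/3, observed is het=0, so p = 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # all-heterozygote table: tail probability by independent enumeration
  enum_p <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    na <- 2 * naa + nab
    hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    pr <- vapply(hets, function(h) {
      x_aa <- (na - h) / 2
      x_bb <- (2 * n - na - h) / 2
      exp(lfactorial(n) - lfactorial(x_aa) - lfactorial(h) -
            lfactorial(x_bb) + h * log(2) +
            lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n))
    }, 0)
    obs <- pr[hets == nab]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  expect_equal(hwe_exact_test(0, 8, 0), enum_p(0, 8, 0), tolerance = 1e-12)
  # random configurations match the oracle and probabilities sum to 1
  set.seed(702)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    na <- sample(1:(2 * n - 1), 1)
    nab <- sample(seq(na %% 2, min(na, 2 * n - na), by = 2), 1)
    naa <- (na - nab) / 2
    nbb <- n - naa - nab
    expect_equal(hwe_exact_test(naa, nab, nbb), enum_p(naa, nab, nbb),
                 tolerance = 1e-12)
  }
  probs <- otterpg:::hwe_het_probabilities(12, 9)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
})

test_that("chi-square HWE variant behaves sensibly", {
  expect_equal(hwe_chisq_test(10, 0, 0), 1)
  # strong het excess is significant under both tests
  expect_lt(hwe_chisq_test(0, 30, 0), 0.01)
  expect_lt(hwe_exact_test(0, 30, 0), 0.01)
})

test_that("LD pruning removes duplicated sites and matches the window oracle", {
  set.seed(703)
  base <- sample(0:2, 12, TRUE)
  other <- rbinom(12, 2, 0.5)
  while (genotype_r2(base, other) >= 0.2) other <- rbinom(12, 2, 0.5)
  geno <- rbind(base, base, other)
  vt <- make_vt(geno, pos = c(1000L, 6000L, 12000L))
  cfg <- prune_config(maf_min = 0, hwe_p_min = 0)
  out <- prune_variants(vt, cfg)
  # duplicate 5 kb apart: later copy removed; independent site kept
  expect_equal(out$sites$pos, c(1000L, 12000L))
  # 200-site fixture equals the explicit window-enumeration oracle
  for (rep in 1:3) {
    n <- 200L
    pos <- sort(sample(1:100000, n))
    block <- cumsum(runif(n) < 0.4)
    anchors <- matrix(sample(0:2, (max(block) + 1) * 15, TRUE),
                      max(block) + 1, 15)
    geno <- anchors[block + 1, ]
    flip <- runif(n) < 0.3
    geno[flip, ] <- pmax(pmin(geno[flip, ] +
                                sample(c(-1, 1), sum(flip) * 15, TRUE),
                              2), 0)
    vt <- make_vt(geno, pos = pos)
    out <- prune_variants(vt, cfg)
    alive <- bf_prune_ld(geno, pos, cfg$window_bp, cfg$step_bp, cfg$r2_max)
    expect_identical(out$sites$pos, pos[alive])
    # post hoc: no surviving pair inside any window reaches the threshold
    kept_pos <- out$sites$pos
    kept_g <- out$geno
    for (s in seq(min(pos), max(pos), by = cfg$step_bp)) {
      w <- which(kept_pos >= s & kept_pos < s + cfg$window_bp)
      if (length(w) < 2) next
      for (i in seq_along(w)[-1])
        for (j in seq_len(i - 1))
          expect_lt(genotype_r2(kept_g[w[i], ], kept_g[w[j], ]),
                    cfg$r2_max)
    }
  }
})

test_that("MAF and HWE filters act before LD pruning", {
  geno <- rbind(rep(c(0L, 1L), c(11, 1)),      # maf 1/24 < 0.10
                rep(c(0L, 2L), c(6, 6)),       # extreme HWE departure
                rbinom(12, 2, 0.5))
  vt <- make_vt(geno, pos = c(1000L, 2000L, 3000L))
  out <- prune_variants(vt, prune_config())
  expect_false(1000L %in% out$sites$pos)
  expect_false(2000L %in% out$sites$pos)
})

test_that("PCA separates clusters and reports ordered variance fractions", {
  a <- c(rep(0L, 30), rep(2L, 10))
  b <- c(rep(2L, 30), rep(0L, 10))
  geno <- cbind(a, a, a, b, b, b)
  vt <- make_vt(geno)
  pc <- pca_genotypes(vt)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # two clusters of identical individuals: PC1 separates, zero spread within
  expect_equal(sd(pc$scores[1:3, 1]), 0, tolerance = 1e-8)
  expect_equal(sd(pc$scores[4:6, 1]), 0, tolerance = 1e-8)
  expect_gt(abs(mean(pc$scores[1:3, 1]) - mean(pc$scores[4:6, 1])), 1)
  # invariance to sample order (scores permute, up to a sign flip)
  perm <- c(4, 1, 6, 2, 3, 5)
  pc2 <- pca_genotypes(subset_samples(vt, vt$samples[perm]))
  for (k in 1:2) {
    direct <- pc$scores[perm, k]
    expect_true(isTRUE(all.equal(pc2$scores[, k], direct,
                                 tolerance = 1e-8,
                                 check.attributes = FALSE)) ||
                  isTRUE(all.equal(pc2$scores[, k], -direct,
                                   tolerance = 1e-8,
                                   check.attributes = FALSE)))
  }
  expect_error(pca_genotypes(make_vt(matrix(2L, 5, 3))), "degenerate")
})

test_that("PCA on the pruned cohort recovers the three planted populations", {
  co <- cohort_default()
  pruned <- prune_variants(co$auto_ingroup)
  pc <- pca_genotypes(pruned)
  set.seed(704)
  km <- kmeans(pc$scores[, 1:2], centers = 3, nstart = 25)
  truth_pop <- co$pop$assignments$population[
    match(rownames(pc$scores), co$pop$assignments$sample)]
  tab <- table(km$cluster, truth_pop)
  expect_equal(sum(tab) - sum(apply(tab, 1, max)), 0)
  .cohorts$pruned <- pruned   # reuse in acceptance checks
})
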