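test_that("heterozygosity is the het-site count over the reference length", {
  geno <- matrix(c(1, 1, 1, 1, 1, 0, 0, 2, 0, 0,
                   0, 0, 0, 2, 2, 0, 0, 0, 0, 0), ncol = 2)
  vt <- make_vt(geno)
  g <- simple_genome(10000)
  h <- heterozygosity(vt, g)
  expect_equal(unname(h), c(5 / 10000, 0))
})

test_that("population pi matches its closed form and the unbiased toggle", {
  # one site, p = 0.5 over 2n = 4 chromosomes
  vt <- make_vt(matrix(c(1L, 1L), 1, 2))
  g <- simple_genome(1)
  pop <- population_map(c("S01", "S02"), c("A", "A"))
  expect_equal(unname(population_pi(vt, pop, g)), 2 * 0.5 * 0.5 * 4 / 3)
  expect_equal(unname(population_pi(vt, pop, g, unbiased = FALSE)), 0.5)
  # monomorphic population
  vt0 <- make_vt(matrix(2L, 3, 2))
  expect_equal(unname(population_pi(vt0, pop, simple_genome(100))), 0)
  expect_error(population_pi(vt, pop, g, populations = "Z"), "Z")
})

test_that("pi and dxy equal the brute-force pairwise-haplotype oracle", {
  set.seed(501)
  for (rep in 1:5) {
    n_hap_a <- 6L; n_hap_b <- 8L; n <- 120L
    hap_a <- matrix(rbinom(n * n_hap_a, 1, runif(n)), n, n_hap_a)
    hap_b <- matrix(rbinom(n * n_hap_b, 1, runif(n)), n, n_hap_b)
    geno <- cbind(hap_to_geno(hap_a), hap_to_geno(hap_b))
    vt <- make_vt(geno)
    g <- simple_genome(5000)
    pop <- population_map(vt$samples,
                          rep(c("A", "B"), c(n_hap_a / 2, n_hap_b / 2)))
    expect_equal(unname(population_pi(vt, pop, g, populations = "A")),
                 bf_pairwise(hap_a, denominator = 5000), tolerance = 1e-12)
    d <- dxy(vt, pop, "A", "B", g)
    expect_equal(d, bf_pairwise(hap_a, hap_b, denominator = 5000),
                 tolerance = 1e-12)
    # symmetry
    expect_identical(d, dxy(vt, pop, "B", "A", g))
  }
})

test_that("dxy handles fixed differences and rejects identical labels", {
  g <- simple_genome(1)
  pop <- population_map(c("S01", "S02"), c("A", "B"))
  vt <- make_vt(matrix(c(2L, 0L), 1, 2))   # fixed difference
  expect_equal(dxy(vt, pop, "A", "B", g), 1)
  vt2 <- make_vt(matrix(c(2L, 0L, 2L, 0L), 2, 2))  # both fixed, equal
  expect_equal(dxy(vt2, pop, "A", "B", simple_genome(10)), 0)
  expect_error(dxy(vt, pop, "A", "A", g), "differ")
})

test_that("da identity holds to machine precision for every pair", {
  expect_equal(da(0.0011, 0.0011, 0.0011), 0)
  expect_equal(da(0.002, 0.001, 0.001), 0.001)
  set.seed(502)
  geno <- matrix(rbinom(200 * 9, 2, 0.4), 200, 9)
  vt <- make_vt(geno)
  pop <- population_map(vt$samples, rep(c("A", "B", "C"), each = 3))
  g <- simple_genome(1e5)
  div <- divergence_summary(vt, pop, g)
  for (i in seq_len(nrow(div$pairs))) {
    expect_equal(div$pairs$da[i],
                 div$pairs$dxy[i] - (div$pi[[div$pairs$pop_a[i]]] +
                                       div$pi[[div$pairs$pop_b[i]]]) / 2,
                 tolerance = 1e-15)
  }
})

test_that("estimated heterozygosity, pi and dxy recover the planted truth", {
  co <- cohort_default()
  truth <- co$truth
  # per-individual heterozygosity within 3 binomial SD of its expectation
  het <- heterozygosity(co$auto_ingroup, co$genome)
  L <- co$genome$reference_length
  freqs <- truth$site_freqs
  auto <- truth$background_sites$chrom %in% c("chr1", "chr2")
  for (s in co$ingroup) {
    k <- match(truth$populations[match(s, truth$samples)],
               colnames(freqs))
    h <- 2 * freqs[auto, k] * (1 - freqs[auto, k])
    sd_count <- sqrt(sum(h * (1 - h)))
    expect_lt(abs(het[[s]] - truth$expected$het[[s]]),
              3 * sd_count / L + 1e-6)  # slack: planted coding sites
  }
  # pi and dxy within 3 SE, SE from parametric replicates of the planted
  # sampling design (50 draws)
  div <- divergence_summary(co$auto_ingroup, co$pop, co$genome)
  pops <- colnames(freqs)
  se <- planted_design_se(truth, L, seed = 9000)
  for (k in seq_along(pops))
    expect_lt(abs(div$pi[[pops[k]]] - truth$expected$pi[[pops[k]]]),
              3 * se$pi[k])
  for (i in seq_len(nrow(div$pairs))) {
    j <- which(se$pair_a == div$pairs$pop_a[i] &
                 se$pair_b == div$pairs$pop_b[i])
    expect_lt(abs(div$pairs$dxy[i] - truth$expected$pairs$dxy[i]),
              3 * se$dxy[j])
  }
})
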