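# shared fixtures and brute-force oracles -------------------------------

# quick variant table: genotypes given, quality fields defaulting to
# comfortably passing values
make_vt <- function(geno, pos = seq_len(nrow(geno)) * 1000L,
                    chrom = "chr1", ref = "A", alt = "G",
                    dp = 99L, gq = 99L, samples = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(geno)))
  variant_table(
    data.frame(chrom = rep_len(chrom, n), pos = pos,
               ref = rep_len(ref, n), alt = rep_len(alt, n),
               stringsAsFactors = FALSE),
    matrix(as.integer(geno), n, ncol(geno)),
    dp = matrix(as.integer(rep_len(dp, n * ncol(geno))), n, ncol(geno)),
    gq = matrix(as.integer(rep_len(gq, n * ncol(geno))), n, ncol(geno)),
    samples = samples)
}

simple_genome <- function(len = 1e7, chrom = "chr1") {
  genome_model(data.frame(chrom = chrom, length = len, is_autosome = TRUE))
}

# cohort cache: expensive simulated cohorts built once per test run
.cohorts <- new.env(parent = emptyenv())

cohort_default <- function() {
  if (is.null(.cohorts$default)) {
    dir <- file.path(tempdir(), "otterpg_cohort_default")
    truth <- simulate_cohort(sim_config(seed = 42), dir)
    vt <- read_vcf(truth$files$vcf)
    genome <- read_genome_model(truth$files$genome)
    pop <- read_population_map(truth$files$pops, outgroup = truth$outgroup)
    filtered <- filter_sites(vt)
    auto <- select_autosomes(filtered, genome)
    ingroup <- pop$assignments$sample[!is.na(pop$assignments$population)]
    .cohorts$default <- list(truth = truth, vt = vt, genome = genome,
                             pop = pop, filtered = filtered, auto = auto,
                             ingroup = ingroup,
                             auto_ingroup = subset_samples(auto, ingroup))
  }
  .cohorts$default
}

cohort_small <- function() {
  if (is.null(.cohorts$small)) {
    dir <- file.path(tempdir(), "otterpg_cohort_small")
    cfg <- sim_config(
      seed = 11,
      samples_per_population = c(5L, 4L, 3L),
      chromosomes = data.frame(chrom = c("chr1", "chr2", "chrX"),
                               length = c(2e6, 2e6, 5e5),
                               is_autosome = c(TRUE, TRUE, FALSE)),
      n_sites = 6000L,
      roh_plan = data.frame(sample = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0)))
    truth <- simulate_cohort(cfg, dir)
    .cohorts$small <- list(truth = truth, dir = dir)
  }
  .cohorts$small
}

# mean per-bp pairwise difference between two haplotype matrices
# (sites x haplotypes, 0/1), the textbook diversity/divergence oracle
bf_pairwise <- function(hap_a, hap_b = NULL, denominator) {
  if (is.null(hap_b)) {
    n <- ncol(hap_a)
    tot <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        tot <- tot + sum(hap_a[, i] != hap_a[, j])
    tot / choose(n, 2) / denominator
  } else {
    tot <- 0
    for (i in seq_len(ncol(hap_a)))
      for (j in seq_len(ncol(hap_b)))
        tot <- tot + sum(hap_a[, i] != hap_b[, j])
    tot / (ncol(hap_a) * ncol(hap_b)) / denominator
  }
}

# pair haplotypes into diploid genotypes, columns 1+2 -> sample 1, ...
hap_to_geno <- function(hap) {
  n <- ncol(hap) / 2
  vapply(seq_len(n), function(i) hap[, 2 * i - 1] + hap[, 2 * i],
         numeric(nrow(hap)))
}

# sampling SEs of the pi / dxy estimators under the planted design:
# parametric replicates drawing, per site and population, the allele
# count of the Hardy-Weinberg samples plus the tract-forced (duplicated
# haplotype) samples exactly as the generator does
planted_design_se <- function(truth, L, B = 50L, seed) {
  auto <- truth$background_sites$chrom %in% c("chr1", "chr2")
  f <- truth$site_freqs[auto, , drop = FALSE]
  pops <- colnames(f)
  n_of <- table(truth$populations)[pops]
  ns <- nrow(f)
  tract_n <- vapply(pops, function(p) {
    members <- truth$samples[truth$populations == p]
    tr <- truth$roh_tracts[truth$roh_tracts$sample %in% members, ,
                           drop = FALSE]
    cnt <- integer(ns)
    for (i in seq_len(nrow(tr))) {
      hit <- truth$background_sites$chrom[auto] == tr$chrom[i] &
        truth$background_sites$pos[auto] >= tr$start[i] &
        truth$background_sites$pos[auto] <= tr$end[i]
      cnt <- cnt + hit
    }
    cnt
  }, integer(ns))
  pairs <- utils::combn(length(pops), 2)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rep_pi <- matrix(0, B, length(pops))
  rep_dxy <- matrix(0, B, ncol(pairs))
  for (b in seq_len(B)) {
    p_hat <- matrix(0, ns, length(pops))
    for (k in seq_along(pops)) {
      n_k <- n_of[[k]]
      c_free <- rbinom(ns, 2 * (n_k - tract_n[, k]), f[, k])
      c_tract <- rbinom(ns, tract_n[, k], f[, k])
      n_alt <- c_free + 2 * c_tract
      p_hat[, k] <- n_alt / (2 * n_k)
      rep_pi[b, k] <- sum(n_alt * (2 * n_k - n_alt)) /
        (n_k * (2 * n_k - 1)) / L
    }
    rep_dxy[b, ] <- apply(pairs, 2, function(ij) {
      sum(p_hat[, ij[1]] * (1 - p_hat[, ij[2]]) +
            p_hat[, ij[2]] * (1 - p_hat[, ij[1]])) / L
    })
  }
  list(pi = apply(rep_pi, 2, sd),
       dxy = apply(rep_dxy, 2, sd),
       pair_a = pops[pairs[1, ]], pair_b = pops[pairs[2, ]])
}

# exhaustive window-enumeration oracle for the ROH eligibility scan
bf_window_scan <- function(geno, params) {
  n <- length(geno)
  w <- params$window_snps
  if (n < w) return(rep(FALSE, n))
  hits <- cover <- integer(n)
  for (s in seq_len(n - w + 1)) {
    win <- s:(s + w - 1)
    g <- geno[win]
    hit <- sum(g == 1L, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(g)) <= params$max_missing_per_window
    cover[win] <- cover[win] + 1L
    if (hit) hits[win] <- hits[win] + 1L
  }
  hits / cover >= params$window_hit_threshold - 1e-12
}

# explicit window-enumeration oracle for greedy LD pruning (applies the
# greedy rule window by window with persistent removals)
bf_prune_ld <- function(geno, pos, window_bp, step_bp, r2_max) {
  alive <- rep(TRUE, length(pos))
  starts <- seq(min(pos), max(pos), by = step_bp)
  for (s in starts) {
    in_win <- which(alive & pos >= s & pos < s + window_bp)
    if (length(in_win) < 2) next
    kept <- integer(0)
    for (j in in_win) {
      drop_j <- FALSE
      for (i in kept)
        if (genotype_r2(geno[i, ], geno[j, ]) >= r2_max - 1e-12) {
          drop_j <- TRUE
          break
        }
      if (drop_j) alive[j] <- FALSE else kept <- c(kept, j)
    }
  }
  alive
}

# write a minimal VCF from raw field rows (list of character vectors)
write_mini_vcf <- function(rows, samples, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}
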