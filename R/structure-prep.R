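#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of the two alt-dosage vectors, the
#' composite (unphased) linkage-disequilibrium measure commonly used for
#' SNP pruning. If either site is monomorphic the correlation is
#' undefined and 0 is returned, so monomorphic sites never trigger LD
#' removal (they are handled by the MAF filter).
#'
#' @param g1,g2 equal-length numeric dosage vectors without missing values
#' @return r-squared in \[0, 1\]
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(0)
  stats::cor(g1, g2)^2
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed genotype counts: conditioning on
#' the allele counts, enumerates every heterozygote count of the same
#' parity, computes the probability of each table under random mating,
#' and returns the two-sided p-value as the summed probability of all
#' tables no more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb counts of the two homozygote classes and the
#'   heterozygote class
#' @return p-value in (0, 1\]
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_aa + n_ab          # minor-or-either allele count; symmetric
  probs <- hwe_het_probabilities(n, n_a)
  obs <- probs[as.character(n_ab)]
  if (is.na(obs)) stop("impossible genotype configuration")
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Probability of each compatible heterozygote count given n genotypes and
# n_a copies of one allele (Levene's conditional distribution). Returned
# as a named vector over heterozygote counts.
hwe_het_probabilities <- function(n, n_a) {
  n_b <- 2 * n - n_a
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nbb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  stats::setNames(exp(logp), hets)
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit alternative to
#' [hwe_exact_test()], without continuity correction.
#'
#' @inheritParams hwe_exact_test
#' @return p-value
#' @export
hwe_chisq_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP thinning configuration
#'
#' Defaults reproduce a standard pre-structure/PCA thinning: remove sites
#' with minor allele frequency below 0.10 or departing from
#' Hardy-Weinberg equilibrium at p < 0.1, then prune one of every pair of
#' sites with r-squared >= 0.2 inside a 20 kb window sliding in 1 kb
#' steps.
#'
#' @param window_bp LD window size in bp
#' @param step_bp window step in bp (must not exceed `window_bp`)
#' @param r2_max prune a pair when its r-squared is >= this value
#' @param hwe_p_min remove sites with HWE p-value < this value
#' @param maf_min remove sites with minor allele frequency < this value
#' @param hwe_test `"exact"` or `"chisq"`
#' @return a list of class `prune_config`
#' @export
prune_config <- function(window_bp = 20000L, step_bp = 1000L, r2_max = 0.2,
                         hwe_p_min = 0.1, maf_min = 0.10,
                         hwe_test = c("exact", "chisq")) {
  stopifnot(r2_max > 0, r2_max <= 1, maf_min >= 0, maf_min < 0.5,
            step_bp <= window_bp, step_bp > 0)
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp), r2_max = r2_max,
                 hwe_p_min = hwe_p_min, maf_min = maf_min,
                 hwe_test = match.arg(hwe_test)),
            class = "prune_config")
}

#' Thin SNPs by MAF, Hardy-Weinberg and windowed LD pruning
#'
#' Filters are applied in a fixed, documented order: minor-allele
#' frequency, then Hardy-Weinberg (all samples pooled), then greedy
#' windowed LD pruning. Windows of `window_bp` advance by `step_bp` along
#' each chromosome; within a window surviving sites are scanned left to
#' right and a site is removed as soon as its r-squared with any earlier
#' kept site of the same window reaches `r2_max`. Removal decisions
#' persist across overlapping windows, which makes the outcome
#' deterministic and equal to enumerating every window explicitly: a site
#' is removed exactly when some kept earlier site shares a window with it
#' and their r-squared reaches the threshold, a condition the
#' implementation evaluates in a single left-to-right pass.
#'
#' @param vt a filtered `variant_table` with no missing genotypes
#' @param cfg a [prune_config()]
#' @return the pruned `variant_table`, site order preserved
#' @export
prune_variants <- function(vt, cfg = prune_config()) {
  g <- vt$geno
  if (anyNA(g)) stop("missing genotypes; filter before pruning")
  p <- rowMeans(g) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= cfg$maf_min
  hwe_fun <- if (cfg$hwe_test == "exact") hwe_exact_test else hwe_chisq_test
  idx_poly <- which(keep)
  if (length(idx_poly)) {
    n_bb <- rowSums(g[idx_poly, , drop = FALSE] == 2L)
    n_ab <- rowSums(g[idx_poly, , drop = FALSE] == 1L)
    n_aa <- ncol(g) - n_bb - n_ab
    pvals <- mapply(hwe_fun, n_aa, n_ab, n_bb)
    keep[idx_poly[pvals < cfg$hwe_p_min]] <- FALSE
  }
  # greedy LD pruning on the survivors, one pass per chromosome
  nsamp <- ncol(g)
  for (chr in unique(vt$sites$chrom)) {
    on_chr <- which(vt$sites$chrom == chr & keep)
    if (length(on_chr) < 2) next
    pos <- vt$sites$pos[on_chr]
    m0 <- pos[1]
    # standardized dosages: r^2(i,j) = sum(z_i * z_j)^2
    gg <- g[on_chr, , drop = FALSE]
    mu <- rowMeans(gg)
    sdv <- sqrt(rowSums((gg - mu)^2))
    z <- (gg - mu) / ifelse(sdv == 0, Inf, sdv)  # monomorphic -> r2 = 0
    alive <- rep(TRUE, length(on_chr))
    kept <- integer(0)
    for (j in seq_along(on_chr)) {
      # earlier kept sites that share at least one window with j: the
      # latest window start at or left of site i is
      # m0 + floor((pos_i - m0)/step)*step; i and j share a window iff
      # pos_j falls within window_bp of that start
      while (length(kept) &&
             m0 + (pos[kept[1]] - m0) %/% cfg$step_bp * cfg$step_bp +
             cfg$window_bp <= pos[j])
        kept <- kept[-1]
      for (i in kept) {
        if (sum(z[i, ] * z[j, ])^2 >= cfg$r2_max - 1e-12) {
          alive[j] <- FALSE
          break
        }
      }
      if (alive[j]) kept <- c(kept, j)
    }
    keep[on_chr[!alive]] <- FALSE
  }
  subset_sites(vt, keep)
}

#' Principal component analysis of a genotype matrix
#'
#' Sites are centred by their mean dosage and scaled by
#' `sqrt(2 p (1 - p))` with `p` the alt-allele frequency (the drift-scale
#' normalization standard in population-genetic PCA); the sample
#' covariance of the normalized matrix is then eigendecomposed.
#' Monomorphic sites carry no information and are dropped.
#'
#' @param vt a `variant_table` with at least two samples and one
#'   polymorphic site, no missing genotypes
#' @param n_components number of components to retain (default: all)
#' @return object of class `pca_result`: `scores` (sample x component
#'   matrix), `explained` (fraction of variance per component,
#'   non-increasing), `sdev`
#' @export
pca_genotypes <- function(vt, n_components = NULL) {
  if (n_samples(vt) < 2) stop("PCA requires at least two samples")
  g <- vt$geno
  if (anyNA(g)) stop("missing genotypes; filter before PCA")
  p <- rowMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("degenerate input: no polymorphic sites")
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  m <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  pc <- stats::prcomp(t(m), center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- if (is.null(n_components)) length(ev) else min(n_components, length(ev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- vt$samples
  structure(list(scores = scores,
                 explained = (ev / sum(ev))[seq_len(k)],
                 sdev = pc$sdev[seq_len(k)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components; PC1 %.2f%%, PC2 %s%% of variance\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1],
              if (length(x$explained) > 1)
                sprintf("%.2f", 100 * x$explained[2]) else "-"))
  invisible(x)
}

#' Write PCA scores with an explained-variance header
#' @param x a `pca_result`
#' @param path output TSV
#' @param n_components columns to write (default 10 or all)
#' @return `path`, invisibly
#' @export
write_pca <- function(x, path, n_components = min(10L, ncol(x$scores))) {
  k <- seq_len(n_components)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# explained_variance_fraction\t%s",
                     paste(format(x$explained[k], digits = 8),
                           collapse = "\t")), con)
  df <- data.frame(sample = rownames(x$scores),
                   x$scores[, k, drop = FALSE], check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
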