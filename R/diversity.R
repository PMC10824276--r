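#' Per-individual genome-wide heterozygosity
#'
#' Counts heterozygous genotypes per sample and divides by the reference
#' genome length, following the convention of reporting heterozygosity per
#' reference bp rather than per callable site. Expects a filtered table
#' with no missing genotypes; any residual missing calls are ignored with
#' a warning.
#'
#' @param vt a filtered `variant_table`
#' @param genome a `genome_model`; `genome$reference_length` is the
#'   denominator
#' @return named numeric vector, heterozygous sites per bp, one entry per
#'   sample
#' @export
heterozygosity <- function(vt, genome) {
  if (genome$reference_length <= 0) stop("reference_length must be positive")
  if (anyNA(vt$geno))
    warning("missing genotypes present; they are ignored in the het count")
  colSums(vt$geno == 1L, na.rm = TRUE) / genome$reference_length
}

# Alt-allele frequency per site within one set of samples.
alt_freq <- function(vt, samples) {
  g <- vt$geno[, samples, drop = FALSE]
  rowMeans(g) / 2
}

#' Within-population nucleotide diversity (pi) per bp
#'
#' Per site the contribution is `2 p (1 - p)` with `p` the alt-allele
#' frequency over the `2n` population chromosomes, optionally multiplied
#' by the small-sample correction `2n / (2n - 1)` (on by default) which
#' makes the estimator equal to the mean pairwise difference between the
#' `2n` haplotypes. Contributions are summed over sites and divided by
#' `genome$reference_length`.
#'
#' @param vt a filtered `variant_table` with no missing genotypes
#' @param pop a `population_map`
#' @param genome a `genome_model`
#' @param unbiased apply the `2n/(2n-1)` correction
#' @param populations which populations to compute (default: all)
#' @return named numeric vector of per-bp diversity by population
#' @export
population_pi <- function(vt, pop, genome, unbiased = TRUE,
                          populations = population_labels(pop)) {
  vapply(populations, function(p) {
    s <- population_samples(pop, p)
    n_chr <- 2 * length(s)
    pf <- alt_freq(vt, s)
    h <- 2 * pf * (1 - pf)
    if (unbiased && n_chr > 1) h <- h * n_chr / (n_chr - 1)
    sum(h) / genome$reference_length
  }, numeric(1))
}

#' Between-population divergence d_xy per bp
#'
#' Average per-site probability that a haplotype drawn from population A
#' differs from one drawn from population B:
#' `p_A (1 - p_B) + p_B (1 - p_A)` summed over sites and divided by the
#' reference length. Symmetric in its two populations.
#'
#' @inheritParams population_pi
#' @param pop_a,pop_b distinct population labels
#' @return per-bp d_xy (scalar)
#' @export
dxy <- function(vt, pop, pop_a, pop_b, genome) {
  if (identical(pop_a, pop_b))
    stop("pop_a and pop_b must differ; use population_pi() for within-population diversity")
  pa <- alt_freq(vt, population_samples(pop, pop_a))
  pb <- alt_freq(vt, population_samples(pop, pop_b))
  sum(pa * (1 - pb) + pb * (1 - pa)) / genome$reference_length
}

#' Net divergence d_a
#'
#' `d_a = d_xy - (pi_A + pi_B) / 2`: the divergence accumulated since the
#' populations split, net of diversity carried through from the ancestral
#' population. May be negative through sampling noise; it is not clipped.
#'
#' @param dxy_value d_xy between the two populations (per bp)
#' @param pi_a,pi_b within-population diversity of each population, on
#'   the same denominator
#' @return per-bp net divergence (scalar)
#' @export
da <- function(dxy_value, pi_a, pi_b) dxy_value - (pi_a + pi_b) / 2

#' All pairwise divergence statistics
#'
#' Convenience wrapper computing pi for every population and d_xy / d_a
#' for every unordered population pair.
#'
#' @inheritParams population_pi
#' @return list with `pi` (named vector) and `pairs` (data.frame with
#'   columns pop_a, pop_b, dxy, da)
#' @export
divergence_summary <- function(vt, pop, genome, unbiased = TRUE) {
  labs <- population_labels(pop)
  pi_vals <- population_pi(vt, pop, genome, unbiased = unbiased)
  pairs <- if (length(labs) >= 2) t(utils::combn(labs, 2)) else
    matrix(character(0), 0, 2)
  out <- data.frame(pop_a = pairs[, 1], pop_b = pairs[, 2],
                    dxy = NA_real_, da = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    d <- dxy(vt, pop, out$pop_a[i], out$pop_b[i], genome)
    out$dxy[i] <- d
    out$da[i] <- da(d, pi_vals[[out$pop_a[i]]], pi_vals[[out$pop_b[i]]])
  }
  list(pi = pi_vals, pairs = out)
}
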