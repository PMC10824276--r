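#' One-way analysis of variance
#'
#' Classic between/within mean-square F test. The degenerate case of zero
#' between- and zero within-group variation is reported as F = 0 with
#' p = 1 rather than NaN.
#'
#' @param values numeric vector of observations
#' @param groups group label for each observation (>= 2 groups, at least
#'   one group with >= 2 observations)
#' @return list of class `anova_oneway`: `F`, `p`, `df1`, `df2`,
#'   `ms_within` and a per-group table `groups` (`group`, `n`, `mean`,
#'   `se`)
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  labs <- unique(groups)
  k <- length(labs)
  n <- length(values)
  if (k < 2) stop("at least two groups required")
  if (n - k < 1) stop("at least one group needs two or more observations")
  means <- tapply(values, groups, mean)[labs]
  ns <- tapply(values, groups, length)[labs]
  sds <- tapply(values, groups, stats::sd)[labs]
  grand <- mean(values)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  msb <- ss_between / df1
  msw <- ss_within / df2
  if (msw == 0 && msb == 0) {
    f <- 0; p <- 1
  } else if (msw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, p = p, df1 = df1, df2 = df2, ms_within = msw,
                 groups = data.frame(group = labs, n = as.integer(ns),
                                     mean = as.numeric(means),
                                     se = as.numeric(sds / sqrt(ns)),
                                     stringsAsFactors = FALSE)),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Tukey-Kramer HSD pairwise comparisons
#'
#' All-pairs comparison after a one-way ANOVA, valid for unequal group
#' sizes. For each pair the studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt( MSW/2 * (1/n_i + 1/n_j) )` and the
#' adjusted p-value is its upper-tail probability under the studentized
#' range distribution with `k` groups and `N - k` error degrees of
#' freedom (`ptukey`). With equal group sizes this reduces to the
#' classical Tukey HSD.
#'
#' @inheritParams anova_oneway
#' @param alpha family-wise significance level used for the
#'   `significant` flag
#' @return list of class `tukey_kramer`: the underlying `anova` and a
#'   `pairs` data.frame (`group_a`, `group_b`, `diff`, `q`, `p_adj`,
#'   `significant`) with one row per unordered pair
#' @export
tukey_kramer <- function(values, groups, alpha = 0.05) {
  an <- anova_oneway(values, groups)
  labs <- an$groups$group
  k <- length(labs)
  cmb <- utils::combn(labs, 2)
  means <- stats::setNames(an$groups$mean, labs)
  ns <- stats::setNames(an$groups$n, labs)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    d <- means[[a]] - means[[b]]
    se <- sqrt(an$ms_within / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- if (se == 0) { if (d == 0) 0 else Inf } else abs(d) / se
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = an$df2, lower.tail = FALSE)
    data.frame(group_a = a, group_b = b, diff = d, q = q, p_adj = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  structure(list(anova = an, alpha = alpha, pairs = do.call(rbind, rows)),
            class = "tukey_kramer")
}

#' @export
print.tukey_kramer <- function(x, ...) {
  print(x$anova)
  cat(sprintf("Tukey-Kramer HSD (alpha = %g):\n", x$alpha))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Compare a per-sample statistic across populations
#'
#' Convenience wrapper running [anova_oneway()] and [tukey_kramer()] on
#' one column of a per-sample table.
#'
#' @param df data.frame with one row per sample
#' @param value name of the numeric column to compare
#' @param group name of the grouping column (default `"population"`)
#' @param alpha family-wise level for [tukey_kramer()]
#' @return a `tukey_kramer` object
#' @export
compare_groups <- function(df, value, group = "population", alpha = 0.05) {
  keep <- !is.na(df[[value]]) & !is.na(df[[group]])
  tukey_kramer(df[[value]][keep], df[[group]][keep], alpha = alpha)
}
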