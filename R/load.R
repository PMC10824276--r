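#' Polarize alleles against a homozygous outgroup
#'
#' Assigns the ancestral allele at each site from the designated outgroup
#' genome: a homozygous-reference outgroup genotype marks the reference
#' allele ancestral, homozygous-alternate marks the alternate ancestral,
#' and a heterozygous or missing outgroup call leaves the site
#' `unclassified` (such sites are excluded from derived-allele counting).
#'
#' @param vt a `variant_table` containing the outgroup sample
#' @param outgroup outgroup sample name
#' @return character vector over sites: `"ref"`, `"alt"` or
#'   `"unclassified"`
#' @export
polarize_alleles <- function(vt, outgroup) {
  if (!(outgroup %in% vt$samples))
    stop("outgroup sample '", outgroup, "' not in variant table")
  g <- vt$geno[, outgroup]
  out <- rep("unclassified", n_sites(vt))
  out[!is.na(g) & g == 0L] <- "ref"
  out[!is.na(g) & g == 2L] <- "alt"
  out
}

#' Per-genome mutation-load summary
#'
#' Counts, for every ingroup sample, the coding sites at which it carries
#' the derived allele, split by functional category (synonymous,
#' nonsynonymous, loss-of-function = stop gain + stop loss), and
#' aggregates Grantham scores over the nonsynonymous derived alleles.
#' Sites with an unclassified ancestral state (outgroup heterozygous or
#' missing) are excluded. The default `"carrier"` counting scores a site
#' once when the sample carries at least one derived copy; `"copies"`
#' weighs heterozygotes 1 and derived homozygotes 2.
#'
#' @param vt a filtered `variant_table` containing the outgroup
#' @param effects one-call-per-site data.frame from [collapse_effects()]
#' @param pop a `population_map` whose `outgroup` names the polarizing
#'   sample
#' @param outgroup outgroup sample name (default: from `pop`)
#' @param mode `"carrier"` or `"copies"`
#' @return data.frame per ingroup sample: `sample`, `population`,
#'   `n_syn`, `n_nonsyn`, `n_lof`, `ratio_ns_s` (`NA` when `n_syn` is 0),
#'   `mean_grantham`, `mean_grantham_deleterious` (score > 50 only) and
#'   `sum_grantham_deleterious`
#' @export
per_genome_load <- function(vt, effects, pop, outgroup = pop$outgroup,
                            mode = c("carrier", "copies")) {
  mode <- match.arg(mode)
  if (is.null(outgroup)) stop("an outgroup sample is required for polarization")
  anc <- polarize_alleles(vt, outgroup)
  site_key <- paste(vt$sites$chrom, vt$sites$pos)
  eff_idx <- match(paste(effects$chrom, effects$pos), site_key)
  if (anyNA(eff_idx)) stop("effect table contains sites absent from the variant table")
  keep <- anc[eff_idx] != "unclassified"
  eff <- effects[keep, , drop = FALSE]
  idx <- eff_idx[keep]
  anc_eff <- anc[idx]
  ingroup <- pop$assignments$sample[!is.na(pop$assignments$population)]
  ingroup <- intersect(vt$samples, ingroup)
  g <- vt$geno[idx, ingroup, drop = FALSE]
  if (anyNA(g)) stop("missing ingroup genotypes at effect sites; filter first")
  derived <- ifelse(matrix(anc_eff == "ref", nrow(g), ncol(g)),
                    g, 2L - g)                    # derived-allele copies
  w <- if (mode == "carrier") (derived > 0) * 1 else derived
  cat_of <- eff$category
  is_nonsyn <- cat_of == "nonsynonymous"
  is_lof <- cat_of %in% c("stop_gain", "stop_loss")
  gs <- eff$grantham
  del <- is_nonsyn & !is.na(gs) & gs > 50
  count_cat <- function(mask) {
    if (!any(mask)) return(stats::setNames(numeric(length(ingroup)), ingroup))
    colSums(w[mask, , drop = FALSE])
  }
  n_syn <- count_cat(cat_of == "synonymous")
  n_nonsyn <- count_cat(is_nonsyn)
  n_lof <- count_cat(is_lof)
  g_weight <- function(mask) {
    if (!any(mask)) return(list(sum = stats::setNames(numeric(length(ingroup)), ingroup),
                                n = stats::setNames(numeric(length(ingroup)), ingroup)))
    ww <- w[mask, , drop = FALSE]
    list(sum = colSums(ww * gs[mask]), n = colSums(ww))
  }
  all_ns <- g_weight(is_nonsyn)
  del_ns <- g_weight(del)
  pop_of <- pop$assignments$population[match(ingroup, pop$assignments$sample)]
  data.frame(sample = ingroup, population = pop_of,
             n_syn = as.numeric(n_syn), n_nonsyn = as.numeric(n_nonsyn),
             n_lof = as.numeric(n_lof),
             ratio_ns_s = ifelse(n_syn > 0, n_nonsyn / n_syn, NA_real_),
             mean_grantham = ifelse(all_ns$n > 0, all_ns$sum / all_ns$n,
                                    NA_real_),
             mean_grantham_deleterious = ifelse(del_ns$n > 0,
                                                del_ns$sum / del_ns$n,
                                                NA_real_),
             sum_grantham_deleterious = as.numeric(del_ns$sum),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Population means and standard errors of load statistics
#'
#' @param load_df data.frame from [per_genome_load()]
#' @return data.frame with one row per (population, statistic):
#'   `population`, `statistic`, `n`, `mean`, `se`
#' @export
summarize_load_by_population <- function(load_df) {
  stats_cols <- setdiff(names(load_df), c("sample", "population"))
  rows <- list()
  for (p in unique(load_df$population)) {
    sub <- load_df[load_df$population == p, , drop = FALSE]
    for (s in stats_cols) {
      v <- sub[[s]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        population = p, statistic = s, n = length(v), mean = mean(v),
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
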