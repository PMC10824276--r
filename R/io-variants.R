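#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF v4.x file (plain or gzipped) with `vcfR` and converts it
#' to the package's [variant_table()] representation. All records are
#' retained, including indels and multiallelic sites, which are flagged
#' (`is_snp`, `is_biallelic`) rather than dropped so that the site filter
#' can report what it removes. Genotypes are stored as alt-allele dosages;
#' any genotype involving a second alternate allele, and any missing call,
#' is stored as `NA`. Absent FORMAT fields (DP, GQ) are recorded as
#' missing, never as zero.
#'
#' @param path VCF file
#' @param samples optional character vector restricting (and ordering) the
#'   samples to load; unknown names are an error.
#' @return a `variant_table`
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(gt), ncol(gt))
  all_samples <- colnames(gt)
  if (!is.null(samples)) {
    miss <- setdiff(samples, all_samples)
    if (length(miss)) stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
    dp <- dp[, samples, drop = FALSE]
    gq <- gq[, samples, drop = FALSE]
    all_samples <- samples
  }
  geno <- gt_to_dosage(gt)
  variant_table(sites, geno,
                dp = matrix(as.integer(round(dp)), nrow(geno), ncol(geno)),
                gq = matrix(as.integer(round(gq)), nrow(geno), ncol(geno)),
                samples = all_samples)
}

# GT string matrix ("0/1", "1|1", "./.", possibly with alleles >1) to
# alt-dosage integers; anything other than a diploid call on alleles
# {0,1} becomes NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".") || !all(al %in% c("0", "1")))
      return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  matrix(out, nrow(gt), ncol(gt), dimnames = dimnames(gt))
}

#' Write a variant table as a plain-text VCF v4.2 file
#'
#' Emits GT:DP:GQ genotype columns. Sites whose dosage is `NA` are written
#' as `./.`; the original multiallelic genotype strings are not recoverable
#' and such sites should normally be filtered before export.
#'
#' @param vt a `variant_table`
#' @param path output path (plain text)
#' @return `path`, invisibly
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$samples), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")[vt$geno + 1L]
  gt[is.na(gt)] <- "./."
  field <- paste(gt,
                 ifelse(is.na(vt$dp), ".", as.character(vt$dp)),
                 ifelse(is.na(vt$gq), ".", as.character(vt$gq)), sep = ":")
  field <- matrix(field, nrow = n_sites(vt))
  body <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref,
                vt$sites$alt, ".", "PASS", ".", "GT:DP:GQ", sep = "\t")
  for (j in seq_len(ncol(field))) body <- paste(body, field[, j], sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Apply the site-level quality filter
#'
#' Retains biallelic SNP sites at which every sample has a called genotype
#' with read depth strictly greater than `min_dp` and genotype quality
#' strictly greater than `min_gq`. The inequalities are deliberately
#' strict (DP > 10, GQ > 20 at the defaults), and a genotype with an
#' absent DP or GQ field fails the corresponding threshold. Filtering is
#' conjunctive per site: a site passes only if every sample passes every
#' rule. Site order is preserved and the operation is idempotent.
#'
#' @param vt a `variant_table`
#' @param min_dp per-genotype depth must exceed this value
#' @param min_gq per-genotype quality must exceed this value
#' @param allow_missing if `TRUE`, missing genotypes are tolerated and the
#'   DP/GQ thresholds are applied to called genotypes only; the default
#'   `FALSE` removes any site with a missing call.
#' @return the filtered `variant_table`, with a `filter_report` attribute:
#'   a data.frame of `(rule, sites_removed)` counts attributing each
#'   removed site to the first rule (in the order not-SNP, multiallelic,
#'   missing genotype, low DP, low GQ) that it violates.
#' @export
filter_sites <- function(vt, min_dp = 10L, min_gq = 20L,
                         allow_missing = FALSE) {
  if (n_sites(vt) == 0) stop("empty variant table")
  miss <- is.na(vt$geno)
  called <- !miss
  dp_ok_g <- !is.na(vt$dp) & vt$dp > min_dp
  gq_ok_g <- !is.na(vt$gq) & vt$gq > min_gq
  snp <- vt$sites$is_snp
  biall <- vt$sites$is_biallelic
  if (allow_missing) {
    no_miss <- rep(TRUE, n_sites(vt))
    dp_ok <- rowSums(called & !dp_ok_g) == 0
    gq_ok <- rowSums(called & !gq_ok_g) == 0
  } else {
    no_miss <- rowSums(miss) == 0
    dp_ok <- rowSums(!dp_ok_g) == 0
    gq_ok <- rowSums(!gq_ok_g) == 0
  }
  pass <- snp & biall & no_miss & dp_ok & gq_ok
  # sequential attribution for the report only; the filter itself is a
  # single conjunction
  first_fail <- rep(NA_character_, n_sites(vt))
  first_fail[!gq_ok] <- "low_GQ"
  first_fail[!dp_ok] <- "low_DP"
  first_fail[!no_miss] <- "missing_genotype"
  first_fail[!biall] <- "multiallelic"
  first_fail[!snp] <- "not_snp"
  rules <- c("not_snp", "multiallelic", "missing_genotype", "low_DP", "low_GQ")
  report <- data.frame(rule = rules,
                       sites_removed = as.integer(table(factor(first_fail,
                                                               rules))),
                       stringsAsFactors = FALSE)
  out <- subset_sites(vt, pass)
  attr(out, "filter_report") <- report
  out
}

#' Restrict a variant table to autosomal sites
#'
#' @param vt a `variant_table`
#' @param genome a `genome_model`; every chromosome present in `vt` must
#'   appear in its chromosome table, otherwise a configuration error is
#'   raised.
#' @return the `variant_table` restricted to chromosomes flagged as
#'   autosomes in `genome`
#' @export
select_autosomes <- function(vt, genome) {
  unknown <- setdiff(unique(vt$sites$chrom), genome$chromosomes$chrom)
  if (length(unknown))
    stop("chromosome(s) absent from genome model: ",
         paste(unknown, collapse = ", "))
  auto <- genome$chromosomes$chrom[genome$chromosomes$is_autosome]
  subset_sites(vt, vt$sites$chrom %in% auto)
}

#' Write the site-filter report emitted by [filter_sites()]
#' @param vt a filtered `variant_table` carrying a `filter_report` attribute
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(vt, path) {
  rep <- attr(vt, "filter_report")
  if (is.null(rep)) stop("variant table carries no filter report")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
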