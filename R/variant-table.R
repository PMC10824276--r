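#' Construct a variant table
#'
#' The central in-memory container of the package: a set of variant sites
#' with a per-sample genotype dosage matrix and the per-genotype quality
#' fields needed for site filtering. Positions follow the VCF convention
#' (1-based); all derived interval arithmetic elsewhere in the package is
#' done on these 1-based inclusive coordinates.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (integer, 1-based), `ref`, `alt` (character allele strings; `alt` may
#'   contain commas for multiallelic records, which are retained but
#'   flagged).
#' @param geno integer matrix, sites x samples, counting alt-allele copies
#'   (0, 1, 2) with `NA` for missing or non-biallelic genotypes.
#' @param dp,gq integer matrices of per-genotype read depth and genotype
#'   quality, same shape as `geno`; `NA` where the FORMAT field is absent.
#' @param samples character vector of sample names (column order of the
#'   matrices).
#'
#' @return An object of class `variant_table` with elements `sites`
#'   (augmented with logical columns `is_snp` and `is_biallelic`), `geno`,
#'   `dp`, `gq` and `samples`.
#' @export
variant_table <- function(sites, geno, dp = NULL, gq = NULL,
                          samples = colnames(geno)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  if (is.null(dp)) dp <- matrix(NA_integer_, nrow(geno), ncol(geno))
  if (is.null(gq)) gq <- matrix(NA_integer_, nrow(geno), ncol(geno))
  stopifnot(identical(dim(dp), dim(geno)), identical(dim(gq), dim(geno)),
            length(samples) == ncol(geno))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  alts <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  sites$is_biallelic <- lengths(alts) == 1L
  allele_lens <- mapply(function(r, a) max(nchar(r), nchar(a)),
                        as.character(sites$ref),
                        vapply(alts, function(a) a[which.max(nchar(a))], ""),
                        USE.NAMES = FALSE)
  sites$is_snp <- allele_lens == 1L
  # positions must be sorted within chromosome so window algorithms can
  # assume ordered input
  ord_ok <- all(unlist(tapply(sites$pos, sites$chrom,
                              function(p) length(p) < 2 || all(diff(p) > 0))))
  if (!ord_ok) stop("positions must be strictly increasing within each chromosome")
  dimnames(geno) <- dimnames(dp) <- dimnames(gq) <- list(NULL, samples)
  structure(list(sites = sites, geno = geno, dp = dp, gq = gq,
                 samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%d chromosomes)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom))))
  cat(sprintf("  biallelic SNPs: %d; multiallelic/indel records: %d\n",
              sum(x$sites$is_biallelic & x$sites$is_snp),
              sum(!(x$sites$is_biallelic & x$sites$is_snp))))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt a `variant_table`
#' @return integer
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname n_sites
#' @export
n_samples <- function(vt) length(vt$samples)

#' Subset a variant table by site index
#'
#' @param vt a `variant_table`
#' @param idx integer or logical site index
#' @return a `variant_table` with the selected sites, order preserved
#' @export
subset_sites <- function(vt, idx) {
  vt$sites <- vt$sites[idx, , drop = FALSE]
  rownames(vt$sites) <- NULL
  vt$geno <- vt$geno[idx, , drop = FALSE]
  vt$dp <- vt$dp[idx, , drop = FALSE]
  vt$gq <- vt$gq[idx, , drop = FALSE]
  vt
}

#' Subset a variant table by sample
#' @param vt a `variant_table`
#' @param samples character vector of sample names to keep
#' @return a `variant_table` restricted to `samples`
#' @export
subset_samples <- function(vt, samples) {
  miss <- setdiff(samples, vt$samples)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  j <- match(samples, vt$samples)
  vt$geno <- vt$geno[, j, drop = FALSE]
  vt$dp <- vt$dp[, j, drop = FALSE]
  vt$gq <- vt$gq[, j, drop = FALSE]
  vt$samples <- samples
  vt
}

#' Genome model: chromosome lengths and denominators
#'
#' Holds the chromosome table and the two genome-size denominators used by
#' downstream statistics: `reference_length` (divisor for per-bp
#' heterozygosity and diversity, the full span of the reference assembly)
#' and `effective_autosomal_size` (divisor for the inbreeding coefficient
#' F_ROH). By default both are derived from the chromosome table:
#' `reference_length` as the total length and `effective_autosomal_size`
#' as the summed length of the autosomes.
#'
#' @param chromosomes data.frame with columns `chrom`, `length` (bp) and
#'   `is_autosome` (logical).
#' @param reference_length total reference span in bp.
#' @param effective_autosomal_size denominator for F_ROH in bp.
#' @return an object of class `genome_model`
#' @export
genome_model <- function(chromosomes,
                         reference_length = sum(chromosomes$length),
                         effective_autosomal_size =
                           sum(chromosomes$length[chromosomes$is_autosome])) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length", "is_autosome") %in% names(chromosomes)),
            all(chromosomes$length > 0),
            reference_length > 0, effective_autosomal_size > 0)
  if (effective_autosomal_size > sum(chromosomes$length))
    stop("effective_autosomal_size exceeds total chromosome length")
  chromosomes$chrom <- as.character(chromosomes$chrom)
  structure(list(chromosomes = chromosomes,
                 reference_length = as.numeric(reference_length),
                 effective_autosomal_size = as.numeric(effective_autosomal_size)),
            class = "genome_model")
}

#' Read a genome model from a TSV file
#'
#' Expected columns: `chrom`, `length`, `is_autosome` (TRUE/FALSE).
#'
#' @param path TSV file path
#' @inheritParams genome_model
#' @return a `genome_model`
#' @export
read_genome_model <- function(path, reference_length = NULL,
                              effective_autosomal_size = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$is_autosome <- as.logical(tab$is_autosome)
  args <- list(chromosomes = tab)
  if (!is.null(reference_length)) args$reference_length <- reference_length
  if (!is.null(effective_autosomal_size))
    args$effective_autosomal_size <- effective_autosomal_size
  do.call(genome_model, args)
}

#' Population map: sample-to-population assignments
#'
#' @param samples character vector of sample names
#' @param populations character vector of population labels, parallel to
#'   `samples`
#' @param outgroup optional name of one sample used only for allele
#'   polarization; it is excluded from population-level statistics.
#' @return an object of class `population_map`
#' @export
population_map <- function(samples, populations, outgroup = NULL) {
  stopifnot(length(samples) == length(populations),
            !anyDuplicated(samples), all(nzchar(populations)))
  if (!is.null(outgroup)) {
    stopifnot(length(outgroup) == 1)
    samples <- c(samples, setdiff(outgroup, samples))
    populations <- c(populations,
                     rep(NA_character_, length(samples) - length(populations)))
    populations[samples == outgroup] <- NA_character_
  }
  structure(list(assignments = data.frame(sample = as.character(samples),
                                          population = as.character(populations),
                                          stringsAsFactors = FALSE),
                 outgroup = outgroup),
            class = "population_map")
}

#' Read a two-column sample/population TSV
#'
#' @param path TSV with columns `sample` and `population` (header
#'   optional; two unnamed columns are accepted).
#' @param outgroup optional outgroup sample name
#' @return a `population_map`
#' @export
read_population_map <- function(path, outgroup = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (identical(tolower(as.character(tab[1, 1])), "sample"))
    tab <- tab[-1, , drop = FALSE]
  pm <- tab[[2]]
  pm[tab[[1]] %in% outgroup] <- NA_character_
  keep <- !is.na(pm)
  population_map(tab[[1]][keep], pm[keep], outgroup = outgroup)
}

#' Samples belonging to one population
#' @param pop a `population_map`
#' @param population population label
#' @return character vector of sample names
#' @export
population_samples <- function(pop, population) {
  s <- pop$assignments$sample[!is.na(pop$assignments$population) &
                                pop$assignments$population == population]
  if (!length(s)) stop("no samples assigned to population '", population, "'")
  s
}

#' Population labels present in a map
#' @param pop a `population_map`
#' @return character vector, in first-appearance order
#' @export
population_labels <- function(pop) {
  unique(pop$assignments$population[!is.na(pop$assignments$population)])
}
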