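#' Site frequency spectrum with hypergeometric projection
#'
#' Builds the histogram of derived- (unfolded) or minor- (folded) allele
#' counts for one population, optionally projected down to a smaller
#' haploid sample size. Projection uses the hypergeometric expectation: a
#' site with derived count `k` out of `2n` chromosomes contributes mass
#' `dhyper(j, k, 2n - k, m)` to bin `j` of the projected size `m`, which
#' is the expected spectrum over all subsamples of `m` chromosomes.
#' Projection is linear and mass-conserving, and projecting to `2n` is
#' the identity.
#'
#' An unfolded spectrum requires allele polarization: supply the outgroup
#' sample name, and sites whose ancestral state is unclassified (outgroup
#' heterozygous or missing, see [polarize_alleles()]) are excluded.
#'
#' @param vt a filtered `variant_table`
#' @param pop a `population_map`
#' @param population population label
#' @param project_to optional even haploid size `m <= 2n` to project to
#'   (odd values are rejected: downstream diploid tools expect even sizes)
#' @param folded build the minor-allele (folded) spectrum instead of the
#'   derived-allele spectrum
#' @param outgroup outgroup sample name, required when `folded = FALSE`
#' @return an object of class `sfs`: list with `population`,
#'   `n_chromosomes` (the size after projection), `counts` (numeric vector
#'   of length `n + 1` unfolded or `floor(n/2) + 1` folded, including the
#'   monomorphic bins), `folded` and `polarized`
#' @export
sfs <- function(vt, pop, population, project_to = NULL, folded = FALSE,
                outgroup = NULL) {
  s <- population_samples(pop, population)
  n_chr <- 2L * length(s)
  g <- vt$geno[, s, drop = FALSE]
  if (anyNA(g)) stop("missing genotypes; filter before building the SFS")
  counts_alt <- rowSums(g)
  if (!folded) {
    if (is.null(outgroup))
      stop("unfolded SFS requires an outgroup sample for polarization")
    anc <- polarize_alleles(vt, outgroup)
    keep <- anc != "unclassified"
    k <- ifelse(anc[keep] == "ref", counts_alt[keep],
                n_chr - counts_alt[keep])
  } else {
    k <- counts_alt
  }
  spec <- tabulate(k + 1L, nbins = n_chr + 1L)
  names(spec) <- 0:n_chr
  m <- n_chr
  if (!is.null(project_to)) {
    if (project_to > n_chr) stop("project_to exceeds 2n")
    if (project_to %% 2 != 0) stop("project_to must be even")
    spec <- project_sfs(spec, n_chr, project_to)
    m <- as.integer(project_to)
  }
  if (folded) spec <- fold_spectrum(spec, m)
  structure(list(population = population, n_chromosomes = m,
                 counts = spec, folded = folded, polarized = !folded),
            class = "sfs")
}

#' Project an unfolded count spectrum to a smaller haploid size
#'
#' @param counts numeric vector of length `n + 1` (bins 0..n)
#' @param n current haploid size
#' @param m target haploid size, `m <= n`
#' @return numeric vector of length `m + 1`
#' @export
project_sfs <- function(counts, n, m) {
  stopifnot(length(counts) == n + 1, m <= n)
  out <- numeric(m + 1)
  for (k in 0:n) {
    if (counts[k + 1] == 0) next
    out <- out + counts[k + 1] * stats::dhyper(0:m, k, n - k, m)
  }
  names(out) <- 0:m
  out
}

fold_spectrum <- function(spec, n) {
  half <- floor(n / 2)
  out <- numeric(half + 1)
  for (j in 0:half) {
    out[j + 1] <- spec[j + 1] +
      if (n - j != j) spec[n - j + 1] else 0
  }
  names(out) <- 0:half
  out
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s site frequency spectrum: population %s, n = %d chromosomes\n",
              if (x$folded) "folded" else "unfolded",
              x$population, x$n_chromosomes))
  print(round(x$counts, 3))
  invisible(x)
}

#' Export a site frequency spectrum
#'
#' Writes the spectrum as a single line of counts preceded by a comment
#' header naming the population and the haploid sample size, the layout
#' expected by SFS-based demographic tools.
#'
#' @param x an `sfs`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_sfs <- function(x, path) {
  writeLines(c(sprintf("# population=%s n_chromosomes=%d folded=%s",
                       x$population, x$n_chromosomes,
                       tolower(as.character(x$folded))),
               paste(format(x$counts, trim = TRUE, digits = 12),
                     collapse = " ")), path)
  invisible(path)
}

#' Read back an exported site frequency spectrum
#' @param path file written by [export_sfs()]
#' @return an `sfs`
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# *", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  counts <- as.numeric(strsplit(lines[2], " +")[[1]])
  n <- as.integer(vals[["n_chromosomes"]])
  names(counts) <- 0:(length(counts) - 1)
  structure(list(population = vals[["population"]], n_chromosomes = n,
                 counts = counts,
                 folded = identical(vals[["folded"]], "true"),
                 polarized = !identical(vals[["folded"]], "true")),
            class = "sfs")
}

#' Export a genotype matrix for external structure analysis
#'
#' Writes the (typically LD-pruned) alt-dosage matrix as a plain TSV,
#' samples in rows and sites in columns, with a `sample` id column -- the
#' integer genotype layout consumed by model-based ancestry tools.
#'
#' @param vt a `variant_table`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
export_structure_input <- function(vt, path) {
  m <- t(vt$geno)
  colnames(m) <- paste(vt$sites$chrom, vt$sites$pos, sep = ":")
  df <- data.frame(sample = vt$samples, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported structure-input genotype matrix
#' @param path file written by [export_structure_input()]
#' @return list with `samples`, `sites` (chrom:pos labels) and `geno`
#'   (samples x sites integer matrix)
#' @export
read_structure_input <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(geno) <- "integer"
  list(samples = df$sample, sites = colnames(geno), geno = geno)
}
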