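#' Parameters for run-of-homozygosity detection
#'
#' Defaults follow the widely used windowed scanning scheme for
#' resequencing data: windows of 20 SNPs tolerate at most one
#' heterozygote and one missing call; a SNP is eligible when at least 1%
#' of the windows covering it are such "hit" windows; called runs must
#' contain at least 20 SNPs and span at least 1,000 kb. Two further knobs
#' default to the scanning scheme's usual values: runs may not be sparser
#' than one SNP per 50 kb and are split at inter-SNP gaps above 1,000 kb.
#'
#' @param min_kb minimum run length in kb
#' @param min_snps_in_run minimum SNP count in a run
#' @param window_snps scanning window size in SNPs
#' @param max_missing_per_window missing calls tolerated per window
#' @param max_het_per_window heterozygotes tolerated per window
#' @param window_hit_threshold minimum fraction of covering windows that
#'   must be hits for a SNP to be eligible, in (0, 1]
#' @param density_kb_per_snp maximum kb per SNP inside a run
#' @param max_gap_kb split a run at gaps larger than this (kb)
#' @return list of class `roh_params`
#' @export
roh_params <- function(min_kb = 1000, min_snps_in_run = 20L,
                       window_snps = 20L, max_missing_per_window = 1L,
                       max_het_per_window = 1L, window_hit_threshold = 0.01,
                       density_kb_per_snp = 50, max_gap_kb = 1000) {
  stopifnot(min_kb > 0, min_snps_in_run > 0, window_snps > 0,
            max_missing_per_window >= 0, max_het_per_window >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            density_kb_per_snp > 0, max_gap_kb > 0)
  structure(list(min_kb = min_kb, min_snps_in_run = as.integer(min_snps_in_run),
                 window_snps = as.integer(window_snps),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 max_het_per_window = as.integer(max_het_per_window),
                 window_hit_threshold = window_hit_threshold,
                 density_kb_per_snp = density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_params")
}

#' Windowed homozygosity scan for one sample on one chromosome
#'
#' Slides a window of `window_snps` consecutive SNPs along the
#' chromosome. A window is a hit when it contains at most
#' `max_het_per_window` heterozygous and at most
#' `max_missing_per_window` missing genotypes. A SNP is eligible when the
#' fraction of windows containing it that are hits reaches
#' `window_hit_threshold`. Chromosomes with fewer SNPs than one window
#' yield no eligible SNPs.
#'
#' @param geno integer dosage vector (0/1/2, `NA` missing) in position
#'   order
#' @param params a [roh_params()]
#' @return logical eligibility vector, one element per SNP
#' @export
roh_window_scan <- function(geno, params = roh_params()) {
  n <- length(geno)
  w <- params$window_snps
  if (n < w) return(rep(FALSE, n))
  het <- as.numeric(!is.na(geno) & geno == 1L)
  mis <- as.numeric(is.na(geno))
  run_sum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  }
  hit <- run_sum(het) <= params$max_het_per_window &
    run_sum(mis) <= params$max_missing_per_window
  n_win <- n - w + 1L
  # windows covering SNP i start in [max(1, i-w+1), min(n_win, i)]
  cs_hit <- c(0, cumsum(hit))
  lo <- pmax(1L, seq_len(n) - w + 1L)
  hi <- pmin(n_win, seq_len(n))
  hits_cover <- cs_hit[hi + 1L] - cs_hit[lo]
  n_cover <- hi - lo + 1L
  hits_cover / n_cover >= params$window_hit_threshold - 1e-12
}

#' Call homozygous runs from eligibility flags
#'
#' Forms maximal runs of consecutive eligible, called, homozygous SNPs
#' (any heterozygote or missing call breaks a run), splits runs at
#' inter-SNP gaps above `max_gap_kb`, and keeps runs that satisfy the
#' minimum SNP count, minimum length and maximum sparseness
#' (`length_kb / n_snps <= density_kb_per_snp`). Run length is measured
#' SNP-to-SNP: `last_pos - first_pos + 1`.
#'
#' @param positions sorted 1-based SNP positions
#' @param geno dosage vector parallel to `positions`
#' @param eligible logical vector from [roh_window_scan()]
#' @param params a [roh_params()]
#' @return data.frame with columns `start_bp`, `end_bp`, `n_snps`,
#'   `length_kb` (zero rows when no run qualifies)
#' @export
roh_call_segments <- function(positions, geno, eligible,
                              params = roh_params()) {
  stopifnot(length(positions) == length(geno),
            length(eligible) == length(geno))
  ok <- eligible & !is.na(geno) & geno != 1L
  segs <- list()
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    # split at large gaps
    gaps <- diff(positions[idx])
    brk <- which(gaps > params$max_gap_kb * 1000)
    piece_start <- c(1L, brk + 1L)
    piece_end <- c(brk, length(idx))
    for (j in seq_along(piece_start)) {
      sub <- idx[piece_start[j]:piece_end[j]]
      len_bp <- positions[sub[length(sub)]] - positions[sub[1]] + 1
      len_kb <- len_bp / 1000
      if (length(sub) >= params$min_snps_in_run &&
          len_kb >= params$min_kb &&
          len_kb / length(sub) <= params$density_kb_per_snp) {
        segs[[length(segs) + 1]] <-
          data.frame(start_bp = positions[sub[1]],
                     end_bp = positions[sub[length(sub)]],
                     n_snps = length(sub), length_kb = len_kb)
      }
    }
  }
  if (!length(segs))
    return(data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  do.call(rbind, segs)
}

#' Detect runs of homozygosity for every sample
#'
#' Runs the windowed scan and segment caller per sample and chromosome.
#' Intended for autosomal input; restrict with [select_autosomes()] first
#' when sex chromosomes are present.
#'
#' @param vt a filtered `variant_table`
#' @param params a [roh_params()]
#' @param samples samples to scan (default: all)
#' @return data.frame of segments: `sample`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_kb`
#' @export
detect_roh <- function(vt, params = roh_params(), samples = vt$samples) {
  out <- list()
  for (chr in unique(vt$sites$chrom)) {
    idx <- which(vt$sites$chrom == chr)
    pos <- vt$sites$pos[idx]
    for (s in samples) {
      g <- vt$geno[idx, s]
      el <- roh_window_scan(g, params)
      segs <- roh_call_segments(pos, g, el, params)
      if (nrow(segs))
        out[[length(out) + 1]] <- cbind(sample = s, chrom = chr, segs,
                                        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample ROH summary statistics
#'
#' SROH: summed run length (kb); NROH: run count; LROH = SROH/NROH (kb,
#' `NA` when no run); F_ROH = SROH / effective autosomal genome size, the
#' genomic inbreeding coefficient.
#'
#' @param segments data.frame from [detect_roh()]
#' @param genome a `genome_model`; `effective_autosomal_size` is the
#'   F_ROH denominator
#' @param samples samples to report (defaults to those present in
#'   `segments`; pass the full cohort to include zero-ROH individuals)
#' @return data.frame: `sample`, `nroh`, `sroh_kb`, `lroh_kb`, `f_roh`
#' @export
summarize_roh <- function(segments, genome, samples = NULL) {
  if (genome$effective_autosomal_size <= 0)
    stop("effective_autosomal_size must be positive")
  if (is.null(samples)) samples <- unique(segments$sample)
  eff_kb <- genome$effective_autosomal_size / 1000
  rows <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    sroh <- sum(seg$length_kb)
    nroh <- nrow(seg)
    data.frame(sample = s, nroh = nroh, sroh_kb = sroh,
               lroh_kb = if (nroh > 0) sroh / nroh else NA_real_,
               f_roh = sroh / eff_kb, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
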