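#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of diploid individuals from several diverged
#' populations plus one outgroup genome, with planted ground truth for
#' every pipeline stage: per-population allele frequencies (drifted from
#' a shared ancestral frequency), forced autozygous tracts, coding
#' variants of known functional consequence and ancestral state, and a
#' plan of deliberately failing sites (low depth, low quality, missing
#' calls, multiallelic and indel records) to exercise the site filter.
#'
#' The defaults emulate a small re-sequencing cohort of a fragmented
#' mammal population: three populations of 13, 4 and 3 individuals plus
#' an outgroup, two 10-Mb autosomes and a 1-Mb sex chromosome,
#' genome-wide heterozygosity near 1e-3 per bp, and inter-population
#' frequency divergence giving pairwise differentiation on the order of
#' Fst ~ 0.05.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   output files
#' @param populations population labels
#' @param samples_per_population integer vector parallel to `populations`
#' @param outgroup_name sample name of the outgroup genome
#' @param chromosomes data.frame (`chrom`, `length`, `is_autosome`)
#' @param target_het target per-bp heterozygosity used to choose the
#'   background site count
#' @param n_sites override the background site count directly (`NULL`:
#'   derived from `target_het`)
#' @param divergence half-width of the uniform perturbation applied to
#'   the ancestral allele frequency in each population
#' @param anc_freq_range range of the ancestral allele frequency draw
#' @param anc_ref_prob probability that the reference allele is the
#'   ancestral one at a background site
#' @param roh_plan data.frame (`sample`, `chrom`, `start`, `end`) of
#'   autozygous tracts to force (`NULL` for the default plan, a
#'   zero-row data.frame for none); the default plants one 2-Mb tract
#'   (10% of the autosomes) in the first sample and 1.5-1.8-Mb tracts in
#'   two others
#' @param coding_plan list of planted coding-variant counts, see Details
#' @param violation_plan list of planted filter-violation counts
#' @param dp_lambda genotype depth is `11 + rpois(dp_lambda)` at passing
#'   sites (defaults emulate ~47x coverage)
#' @param gq_range range of genotype qualities at passing sites
#'
#' @details `coding_plan` fields: `n_syn`, `n_nonsyn`, `n_stop_gain`,
#' `n_stop_loss` (counts of classified coding variants), `n_outgroup_het`
#' and `n_outgroup_missing` (coding sites whose outgroup call is
#' heterozygous or missing, so their ancestral state is unclassified),
#' `derived_freq_range` (per-population derived-allele frequency draw),
#' `alt_ancestral_every` (every k-th classifiable non-LoF site has the
#' alternate allele ancestral), `n_genes`, `chrom`, `region_start`.
#' Nonsynonymous sites cycle through a fixed catalogue of codon changes
#' whose Grantham scores (5, 10, 50, 53, 58, 101, 126, 215) cover the
#' conservative/moderate/radical class boundaries reachable by a single
#' nucleotide change.
#'
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       populations = c("pop1", "pop2", "pop3"),
                       samples_per_population = c(13L, 4L, 3L),
                       outgroup_name = "outgroup1",
                       chromosomes = data.frame(
                         chrom = c("chr1", "chr2", "chrX"),
                         length = c(10e6, 10e6, 1e6),
                         is_autosome = c(TRUE, TRUE, FALSE)),
                       target_het = 1e-3,
                       n_sites = NULL,
                       divergence = 0.2,
                       anc_freq_range = c(0.05, 0.95),
                       anc_ref_prob = 0.8,
                       roh_plan = NULL,
                       coding_plan = list(),
                       violation_plan = list(),
                       dp_lambda = 36,
                       gq_range = c(30L, 99L)) {
  stopifnot(length(populations) == length(samples_per_population),
            all(samples_per_population >= 1),
            divergence >= 0, divergence < 0.5)
  samples <- unlist(mapply(function(p, n) sprintf("%s_%02d", p, seq_len(n)),
                           populations, samples_per_population,
                           SIMPLIFY = FALSE), use.names = FALSE)
  if (is.null(roh_plan)) {
    first <- sprintf("%s_01", populations)
    roh_plan <- data.frame(
      sample = c(first[1],
                 if (length(first) > 1) rep(first[2], 2) else NULL,
                 if (length(first) > 2) first[3] else NULL),
      chrom = c("chr1", "chr1", "chr2", "chr2")[seq_len(
        1 + 2 * (length(first) > 1) + (length(first) > 2))],
      start = c(2000001, 5000001, 1000001, 5000001)[seq_len(
        1 + 2 * (length(first) > 1) + (length(first) > 2))],
      end = c(4000000, 6500000, 2600000, 6800000)[seq_len(
        1 + 2 * (length(first) > 1) + (length(first) > 2))],
      stringsAsFactors = FALSE)
  }
  stopifnot(all(roh_plan$sample %in% samples),
            all(roh_plan$chrom %in% chromosomes$chrom))
  if (nrow(roh_plan)) {
    len_of <- stats::setNames(chromosomes$length, chromosomes$chrom)
    stopifnot(all(roh_plan$start >= 1),
              all(roh_plan$end <= len_of[roh_plan$chrom]),
              all(roh_plan$end > roh_plan$start))
  }
  cp_default <- list(n_syn = 30L, n_nonsyn = 18L, n_stop_gain = 4L,
                     n_stop_loss = 2L, n_outgroup_het = 3L,
                     n_outgroup_missing = 3L,
                     derived_freq_range = c(0.1, 0.6),
                     alt_ancestral_every = 5L,
                     n_genes = 6L, chrom = "chr2", region_start = 100000L)
  coding_plan <- utils::modifyList(cp_default, coding_plan)
  vp_default <- list(n_dp = 4L, n_gq = 4L, n_missing = 4L,
                     n_multiallelic = 4L, n_indel = 4L,
                     chrom = "chr1", region = c(1L, 50000L))
  violation_plan <- utils::modifyList(vp_default, violation_plan)
  structure(list(seed = as.integer(seed), populations = populations,
                 samples_per_population = as.integer(samples_per_population),
                 samples = samples, outgroup_name = outgroup_name,
                 chromosomes = chromosomes, target_het = target_het,
                 n_sites = n_sites, divergence = divergence,
                 anc_freq_range = anc_freq_range,
                 anc_ref_prob = anc_ref_prob, roh_plan = roh_plan,
                 coding_plan = coding_plan, violation_plan = violation_plan,
                 dp_lambda = dp_lambda, gq_range = gq_range),
            class = "sim_config")
}

# codon-change catalogue used to realize planted consequences; all are
# single-nucleotide edits of the (coding-strand) reference codon
.syn_catalog <- list(
  list(codon = "GAA", pos = 3L, alt = "G"),   # Glu -> Glu
  list(codon = "CTG", pos = 3L, alt = "A"),   # Leu -> Leu
  list(codon = "GGT", pos = 3L, alt = "C"),   # Gly -> Gly
  list(codon = "TCA", pos = 3L, alt = "G"))   # Ser -> Ser
.nonsyn_catalog <- list(
  list(codon = "CTT", pos = 1L, alt = "A", score = 5L),    # Leu -> Ile
  list(codon = "ATT", pos = 3L, alt = "G", score = 10L),   # Ile -> Met
  list(codon = "GTT", pos = 1L, alt = "T", score = 50L),   # Val -> Phe
  list(codon = "CAA", pos = 1L, alt = "A", score = 53L),   # Gln -> Lys
  list(codon = "GCT", pos = 1L, alt = "A", score = 58L),   # Ala -> Thr
  list(codon = "CGG", pos = 1L, alt = "T", score = 101L),  # Arg -> Trp
  list(codon = "GAT", pos = 2L, alt = "C", score = 126L),  # Asp -> Ala
  list(codon = "TGT", pos = 3L, alt = "G", score = 215L))  # Cys -> Trp
.stop_gain_catalog <- list(
  list(codon = "TAC", pos = 3L, alt = "A"),   # Tyr -> stop
  list(codon = "TGG", pos = 3L, alt = "A"))   # Trp -> stop
.stop_loss_edit <- list(codon = "TAA", pos = 2L, alt = "T")  # stop -> Leu

.sense_codons <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"],
  c("ATG"))  # avoid planting over start-like codons, cosmetic only

#' Generate a synthetic cohort with planted ground truth
#'
#' Writes a multi-sample VCF, reference FASTA, GFF3 gene annotation,
#' sample-to-population TSV and genome-model TSV into `out_dir`, and
#' returns the planted truth. Background sites are drawn per population
#' from drifted allele frequencies under Hardy-Weinberg genotype
#' proportions, except inside planted autozygous tracts where each
#' genotype is forced homozygous for a single sampled haplotype. Coding
#' variants realize the consequence categories of the coding plan in
#' synthetic two-exon genes (half on the minus strand); the outgroup is
#' emitted homozygous for the planted ancestral allele except at the
#' sites planted heterozygous or missing. Deliberate filter violations
#' (depth and quality exactly at the non-passing boundary, missing calls,
#' multiallelic and indel records) are placed in a reserved region.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory (created if needed)
#' @return invisible list of class `synthetic_truth`; see Details
#' @details The returned truth contains `files` (paths), `samples`,
#'   `populations` (per-sample labels), `site_freqs` (per-population
#'   allele frequencies of background sites), `expected` (per-sample
#'   expected heterozygosity, per-population pi, pairwise dxy/da implied
#'   by the planted frequencies), `roh_tracts`, `coding` (per planted
#'   coding site: position, category, Grantham score, ancestral allele,
#'   outgroup state), `load` (per-sample derived-allele counts by
#'   category, carrier counting), and `filter` (per site: passes the
#'   default strict filter or not, with the violated rule).
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  chroms <- cfg$chromosomes
  chroms$chrom <- as.character(chroms$chrom)
  total_len <- sum(chroms$length)
  pops <- cfg$populations
  n_pop <- length(pops)
  samples <- cfg$samples
  pop_of_sample <- rep(pops, cfg$samples_per_population)
  n_ing <- length(samples)
  outg <- cfg$outgroup_name

  ## ---- reference sequences (character vectors of single bases) ----
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(stats::setNames(chroms$length, chroms$chrom),
                 function(l) sample(bases, l, replace = TRUE))

  ## ---- synthetic genes and planted coding sites ----
  genes <- build_genes(cfg, seqs)
  seqs <- genes$seqs
  coding <- genes$coding          # data.frame of planted coding sites
  gene_region <- genes$region     # region to exclude from background

  ## ---- background sites ----
  mean_h <- {  # expected per-site 2p(1-p) under the planted frequency draw
    a <- cfg$anc_freq_range
    ep <- mean(a); ep2 <- (a[2] - a[1])^2 / 12 + ep^2 +
      cfg$divergence^2 / 3
    2 * (ep - ep2)
  }
  n_bg <- if (!is.null(cfg$n_sites)) as.integer(cfg$n_sites) else
    as.integer(round(cfg$target_het * total_len / mean_h))
  bg <- list()
  for (ci in seq_len(nrow(chroms))) {
    chr <- chroms$chrom[ci]
    n_c <- round(n_bg * chroms$length[ci] / total_len)
    excl_lo <- excl_hi <- integer(0)
    if (chr == cfg$violation_plan$chrom) {
      excl_lo <- c(excl_lo, cfg$violation_plan$region[1])
      excl_hi <- c(excl_hi, cfg$violation_plan$region[2])
    }
    if (chr == gene_region$chrom) {
      excl_lo <- c(excl_lo, gene_region$start)
      excl_hi <- c(excl_hi, gene_region$end)
    }
    ok_pos <- setdiff(seq_len(chroms$length[ci]),
                      unlist(mapply(seq, excl_lo, excl_hi,
                                    SIMPLIFY = FALSE)))
    pos <- sort(sample(ok_pos, n_c))
    bg[[chr]] <- data.frame(chrom = chr, pos = pos, stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, bg)
  rownames(bg) <- NULL
  n_sites_bg <- nrow(bg)
  # alleles: ref from the reference sequence, alt a different base
  ref_bg <- mapply(function(chr, p) seqs[[chr]][p], bg$chrom, bg$pos,
                   USE.NAMES = FALSE)
  alt_bg <- vapply(ref_bg, function(r) sample(setdiff(bases, r), 1), "",
                   USE.NAMES = FALSE)
  # frequencies: shared ancestral, drifted per population
  p_anc <- stats::runif(n_sites_bg, cfg$anc_freq_range[1],
                        cfg$anc_freq_range[2])
  freqs <- vapply(pops, function(p)
    pmin(pmax(p_anc + stats::runif(n_sites_bg, -cfg$divergence,
                                   cfg$divergence), 0.02), 0.98),
    numeric(n_sites_bg))
  # genotypes under HWE within population
  g_bg <- matrix(0L, n_sites_bg, n_ing, dimnames = list(NULL, samples))
  for (k in seq_len(n_pop)) {
    cols <- which(pop_of_sample == pops[k])
    g_bg[, cols] <- stats::rbinom(n_sites_bg * length(cols), 2, freqs[, k])
  }
  # forced autozygous tracts: homozygous for one sampled haplotype
  in_tract <- matrix(FALSE, n_sites_bg, n_ing,
                     dimnames = list(NULL, samples))
  for (t in seq_len(nrow(cfg$roh_plan))) {
    tr <- cfg$roh_plan[t, ]
    idx <- which(bg$chrom == tr$chrom & bg$pos >= tr$start &
                   bg$pos <= tr$end)
    if (!length(idx)) next
    k <- match(pop_of_sample[match(tr$sample, samples)], pops)
    hap <- stats::rbinom(length(idx), 1, freqs[idx, k])
    g_bg[idx, tr$sample] <- 2L * hap
    in_tract[idx, tr$sample] <- TRUE
  }
  # outgroup: homozygous for the planted ancestral allele
  anc_bg <- ifelse(stats::runif(n_sites_bg) < cfg$anc_ref_prob, "ref", "alt")
  g_out_bg <- ifelse(anc_bg == "ref", 0L, 2L)

  ## ---- genotypes at planted coding sites ----
  n_cod <- nrow(coding)
  g_cod <- matrix(0L, n_cod, n_ing, dimnames = list(NULL, samples))
  dfr <- cfg$coding_plan$derived_freq_range
  derived_freq <- matrix(stats::runif(n_cod * n_pop, dfr[1], dfr[2]),
                         n_cod, n_pop)
  for (k in seq_len(n_pop)) {
    p_alt <- ifelse(coding$ancestral == "alt",
                    1 - derived_freq[, k], derived_freq[, k])
    cols <- which(pop_of_sample == pops[k])
    g_cod[, cols] <- stats::rbinom(n_cod * length(cols), 2, p_alt)
  }
  g_out_cod <- ifelse(coding$outgroup_state == "hom_ref", 0L,
                      ifelse(coding$outgroup_state == "hom_alt", 2L,
                             ifelse(coding$outgroup_state == "het", 1L,
                                    NA_integer_)))
  p_alt_cod <- vapply(seq_len(n_pop), function(k)
    ifelse(coding$ancestral == "alt", 1 - derived_freq[, k],
           derived_freq[, k]), numeric(n_cod))

  ## ---- planted load truth (carrier counting, bookkeeping only) ----
  classified <- coding$ancestral %in% c("ref", "alt")
  derived_copies <- ifelse(matrix(coding$ancestral == "ref", n_cod, n_ing),
                           g_cod, 2L - g_cod)
  carrier <- derived_copies > 0 & classified
  cat_mask <- function(cats) coding$category %in% cats & classified
  score <- coding$grantham
  del <- cat_mask("nonsynonymous") & !is.na(score) & score > 50
  load_truth <- data.frame(
    sample = samples, population = pop_of_sample,
    n_syn = colSums(carrier[cat_mask("synonymous"), , drop = FALSE]),
    n_nonsyn = colSums(carrier[cat_mask("nonsynonymous"), , drop = FALSE]),
    n_lof = colSums(carrier[cat_mask(c("stop_gain", "stop_loss")), ,
                            drop = FALSE]),
    sum_grantham_deleterious =
      colSums(carrier[del, , drop = FALSE] * score[del]),
    stringsAsFactors = FALSE, row.names = NULL)

  ## ---- violation records ----
  viol <- build_violations(cfg, seqs, samples, pop_of_sample)

  ## ---- expected (planted) summary statistics ----
  # the expectations describe the autosomal sites that survive the strict
  # default filter: all background sites plus the planted coding sites
  # whose outgroup genotype is not missing
  auto_bg <- bg$chrom %in% chroms$chrom[chroms$is_autosome]
  cod_keep <- coding$outgroup_state != "missing"
  h_site <- 2 * freqs * (1 - freqs)          # per site x population
  h_cod <- 2 * p_alt_cod * (1 - p_alt_cod)
  het_expected <- vapply(seq_len(n_ing), function(j) {
    k <- match(pop_of_sample[j], pops)
    sum(h_site[auto_bg & !in_tract[, j], k]) + sum(h_cod[cod_keep, k])
  }, numeric(1)) / total_len
  # exact expectation of the unbiased pairwise estimator: a forced
  # autozygous sample contributes one identical haplotype pair, shrinking
  # the per-site expectation by t / (n (2n - 1)) with t tract samples
  pi_expected <- vapply(seq_len(n_pop), function(k) {
    in_pop <- pop_of_sample == pops[k]
    n_k <- sum(in_pop)
    t_site <- rowSums(in_tract[, in_pop, drop = FALSE])
    shrink <- 1 - t_site / (n_k * (2 * n_k - 1))
    (sum(h_site[auto_bg, k] * shrink[auto_bg]) +
       sum(h_cod[cod_keep, k])) / total_len
  }, 0)
  names(pi_expected) <- pops
  pair_idx <- utils::combn(n_pop, 2)
  dxy_expected <- apply(pair_idx, 2, function(ij) {
    pa <- c(freqs[auto_bg, ij[1]], p_alt_cod[cod_keep, ij[1]])
    pb <- c(freqs[auto_bg, ij[2]], p_alt_cod[cod_keep, ij[2]])
    sum(pa * (1 - pb) + pb * (1 - pa)) / total_len
  })
  da_expected <- apply(pair_idx, 2, function(ij) {
    sum((c(freqs[auto_bg, ij[1]], p_alt_cod[cod_keep, ij[1]]) -
           c(freqs[auto_bg, ij[2]], p_alt_cod[cod_keep, ij[2]]))^2) /
      total_len
  })
  expected <- list(
    het = stats::setNames(het_expected, samples),
    pi = pi_expected,
    pairs = data.frame(pop_a = pops[pair_idx[1, ]],
                       pop_b = pops[pair_idx[2, ]],
                       dxy = dxy_expected, da = da_expected,
                       stringsAsFactors = FALSE))

  ## ---- assemble and write the VCF ----
  dp_draw <- function(n) 11L + stats::rpois(n, cfg$dp_lambda)
  gq_draw <- function(n) sample(seq(cfg$gq_range[1], cfg$gq_range[2]),
                                n, replace = TRUE)
  all_samples <- c(samples, outg)
  n_all <- length(all_samples)
  make_records <- function(site_df, geno, g_out) {
    n <- nrow(site_df)
    g <- cbind(geno, g_out)
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], n, n_all)
    gt[is.na(g)] <- "./."
    dp <- matrix(as.character(dp_draw(n * n_all)), n, n_all)
    gq <- matrix(as.character(gq_draw(n * n_all)), n, n_all)
    dp[is.na(g)] <- "."
    gq[is.na(g)] <- "."
    list(sites = site_df, gt = gt, dp = dp, gq = gq)
  }
  rec_bg <- make_records(data.frame(chrom = bg$chrom, pos = bg$pos,
                                    ref = ref_bg, alt = alt_bg,
                                    stringsAsFactors = FALSE),
                         g_bg, g_out_bg)
  rec_cod <- make_records(data.frame(chrom = coding$chrom, pos = coding$pos,
                                     ref = coding$ref, alt = coding$alt,
                                     stringsAsFactors = FALSE),
                          g_cod, g_out_cod)
  tag <- function(df, src) { df$src <- rep(src, nrow(df)); df }
  sites_all <- rbind(tag(rec_bg$sites, "background"),
                     tag(rec_cod$sites, "coding"),
                     tag(viol$sites, "violation"))
  gt_all <- rbind(rec_bg$gt, rec_cod$gt, viol$gt)
  dp_all <- rbind(rec_bg$dp, rec_cod$dp, viol$dp)
  gq_all <- rbind(rec_bg$gq, rec_cod$gq, viol$gq)
  ord <- order(match(sites_all$chrom, chroms$chrom), sites_all$pos)
  sites_all <- sites_all[ord, , drop = FALSE]
  gt_all <- gt_all[ord, , drop = FALSE]
  dp_all <- dp_all[ord, , drop = FALSE]
  gq_all <- gq_all[ord, , drop = FALSE]

  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                fasta = file.path(out_dir, "reference.fa"),
                gff = file.path(out_dir, "genes.gff3"),
                pops = file.path(out_dir, "pops.tsv"),
                genome = file.path(out_dir, "genome.tsv"))
  con <- file(paths$vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chroms$chrom,
                       chroms$length),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", all_samples), collapse = "\t")), con)
  body <- paste(sites_all$chrom, sites_all$pos, ".", sites_all$ref,
                sites_all$alt, ".", "PASS", ".", "GT:DP:GQ", sep = "\t")
  fields <- matrix(paste(gt_all, dp_all, gq_all, sep = ":"),
                   nrow(gt_all), n_all)
  for (j in seq_len(n_all)) body <- paste(body, fields[, j], sep = "\t")
  writeLines(body, con)
  close(con)

  ## ---- reference FASTA, GFF3, tables ----
  dna <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(dna) <- chroms$chrom
  Biostrings::writeXStringSet(dna, paths$fasta, width = 80L)
  write_sim_gff3(genes$models, paths$gff)
  utils::write.table(data.frame(sample = all_samples,
                                population = c(pop_of_sample, "outgroup")),
                     paths$pops, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(chroms, paths$genome, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## ---- per-site strict-filter truth ----
  filter_truth <- data.frame(
    chrom = sites_all$chrom, pos = sites_all$pos,
    pass = sites_all$src != "violation" &
      !(paste(sites_all$chrom, sites_all$pos) %in%
          paste(coding$chrom, coding$pos)[coding$outgroup_state == "missing"]),
    stringsAsFactors = FALSE)

  invisible(structure(list(
    config = cfg, files = paths, samples = samples,
    populations = pop_of_sample, outgroup = outg,
    background_sites = bg, site_freqs = freqs, ancestral_background = anc_bg,
    genotypes = {  # truth dosage matrix in VCF site order (NA: no dosage)
      g_full <- rbind(cbind(g_bg, g_out_bg), cbind(g_cod, g_out_cod),
                      viol$dosage)
      colnames(g_full) <- all_samples
      g_full[ord, , drop = FALSE]
    },
    expected = expected, roh_tracts = cfg$roh_plan, coding = coding,
    load = load_truth, filter = filter_truth),
    class = "synthetic_truth"))
}

# Build synthetic two-exon genes, plant the coding sites of the plan,
# and splice the gene sequences into the chromosome base vectors.
build_genes <- function(cfg, seqs) {
  cp <- cfg$coding_plan
  chr <- cp$chrom
  n_genes <- cp$n_genes
  exon1_codons <- 60L
  codons_per_gene <- 121L  # includes the terminal stop codon
  intron_bp <- 200L
  spacing <- 10000L
  # per-gene codon matrix of random sense codons, stop at the end
  gene_models <- list()
  plant <- list()  # planted coding-site rows
  # build the queue of planted sites: category + edit description
  mk <- function(n, cat, catalog) {
    if (n == 0) return(NULL)
    lapply(seq_len(n), function(i) {
      e <- catalog[[(i - 1) %% length(catalog) + 1]]
      list(category = cat, edit = e,
           grantham = if (cat == "nonsynonymous") e$score else NA_integer_)
    })
  }
  queue <- c(mk(cp$n_syn, "synonymous", .syn_catalog),
             mk(cp$n_nonsyn, "nonsynonymous", .nonsyn_catalog),
             mk(cp$n_stop_gain, "stop_gain", .stop_gain_catalog),
             mk(cp$n_outgroup_het, "synonymous", .syn_catalog),
             mk(cp$n_outgroup_missing, "synonymous", .syn_catalog))
  out_state <- c(rep(NA, cp$n_syn + cp$n_nonsyn + cp$n_stop_gain),
                 rep("het", cp$n_outgroup_het),
                 rep("missing", cp$n_outgroup_missing))
  # stop-loss edits go on dedicated genes' terminal codons
  n_stop_loss <- cp$n_stop_loss
  if (n_stop_loss > n_genes) stop("more stop-loss sites than genes")
  per_gene <- ceiling(length(queue) / n_genes)
  max_slots <- (codons_per_gene - 2) %/% 2  # planted codons 2, 4, ...
  if (per_gene > max_slots)
    stop("coding plan too large for the configured genes")
  qi <- 1L
  classifiable_seen <- 0L
  for (gi in seq_len(n_genes)) {
    codons <- sample(.sense_codons, codons_per_gene - 1, replace = TRUE)
    codons <- c(codons, "TAA")
    strand <- if (gi %% 2 == 1) "+" else "-"
    slots <- seq(2L, by = 2L, length.out = min(per_gene, max_slots))
    gene_sites <- list()
    for (s in slots) {
      if (qi > length(queue)) break
      item <- queue[[qi]]
      codons[s] <- item$edit$codon
      anc <- "ref"
      st <- out_state[qi]
      if (is.na(st)) {
        if (item$category %in% c("synonymous", "nonsynonymous")) {
          classifiable_seen <- classifiable_seen + 1L
          if (classifiable_seen %% cp$alt_ancestral_every == 0) anc <- "alt"
        }
        st <- if (anc == "ref") "hom_ref" else "hom_alt"
      } else {
        anc <- "unclassified"
      }
      gene_sites[[length(gene_sites) + 1]] <-
        list(codon_index = s, edit = item$edit, category = item$category,
             grantham = item$grantham, ancestral = anc, outgroup_state = st)
      qi <- qi + 1L
    }
    if (gi > n_genes - n_stop_loss) {
      codons[codons_per_gene] <- .stop_loss_edit$codon  # TAA already
      gene_sites[[length(gene_sites) + 1]] <-
        list(codon_index = codons_per_gene, edit = .stop_loss_edit,
             category = "stop_loss", grantham = NA_integer_,
             ancestral = "ref", outgroup_state = "hom_ref")
    }
    coding_seq <- paste(codons, collapse = "")
    l1 <- exon1_codons * 3L
    l2 <- nchar(coding_seq) - l1
    gstart <- cp$region_start + (gi - 1L) * spacing
    # genomic layout: [exonA][intron][exonB]
    if (strand == "+") {
      exonA <- substr(coding_seq, 1, l1); exonB <- substr(coding_seq, l1 + 1,
                                                          nchar(coding_seq))
    } else {
      exonA <- revcomp(substr(coding_seq, l1 + 1, nchar(coding_seq)))
      exonB <- revcomp(substr(coding_seq, 1, l1))
    }
    a_start <- gstart; a_end <- gstart + nchar(exonA) - 1L
    b_start <- a_end + intron_bp + 1L; b_end <- b_start + nchar(exonB) - 1L
    seqs[[chr]][a_start:a_end] <- strsplit(exonA, "")[[1]]
    seqs[[chr]][b_start:b_end] <- strsplit(exonB, "")[[1]]
    # genomic coordinates of each planted site
    for (site in gene_sites) {
      cpos <- (site$codon_index - 1L) * 3L + site$edit$pos  # coding coord
      if (strand == "+") {
        gpos <- if (cpos <= l1) a_start + cpos - 1L else
          b_start + (cpos - l1) - 1L
        ref <- substr(site$edit$codon, site$edit$pos, site$edit$pos)
        alt <- site$edit$alt
      } else {
        # coding exon1 (cpos <= l1) sits in genomic exonB, reversed
        gpos <- if (cpos <= l1) b_end - cpos + 1L else
          a_end - (cpos - l1) + 1L
        ref <- revcomp(substr(site$edit$codon, site$edit$pos, site$edit$pos))
        alt <- revcomp(site$edit$alt)
      }
      plant[[length(plant) + 1]] <- data.frame(
        chrom = chr, pos = gpos, ref = ref, alt = alt,
        gene = sprintf("gene%d", gi), strand = strand,
        codon_index = site$codon_index, category = site$category,
        grantham = site$grantham, ancestral = site$ancestral,
        outgroup_state = site$outgroup_state, stringsAsFactors = FALSE)
    }
    gene_models[[gi]] <- list(
      id = sprintf("gene%d", gi), chrom = chr, strand = strand,
      exons = data.frame(start = c(a_start, b_start),
                         end = c(a_end, b_end)))
  }
  if (qi <= length(queue)) stop("coding plan could not be fully placed")
  coding <- do.call(rbind, plant)
  coding <- coding[order(coding$pos), , drop = FALSE]
  rownames(coding) <- NULL
  region_end <- cp$region_start + n_genes * spacing
  list(seqs = seqs, coding = coding, models = gene_models,
       region = list(chrom = chr, start = cp$region_start - 1000L,
                     end = region_end + 1000L))
}

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

# Deliberately non-passing records for the site filter.
build_violations <- function(cfg, seqs, samples, pop_of_sample) {
  vp <- cfg$violation_plan
  n_v <- vp$n_dp + vp$n_gq + vp$n_missing + vp$n_multiallelic + vp$n_indel
  type <- rep(c("dp_low", "gq_low", "missing", "multiallelic", "indel"),
              c(vp$n_dp, vp$n_gq, vp$n_missing, vp$n_multiallelic,
                vp$n_indel))
  if (n_v == 0)
    return(list(sites = data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0)),
                gt = matrix("", 0, length(samples) + 1),
                dp = matrix("", 0, length(samples) + 1),
                gq = matrix("", 0, length(samples) + 1),
                dosage = matrix(0L, 0, length(samples) + 1)))
  pos <- seq(vp$region[1] + 999L, by = 2000L, length.out = n_v)
  stopifnot(max(pos) + 1 <= vp$region[2])
  bases <- c("A", "C", "G", "T")
  n_all <- length(samples) + 1L
  ref <- alt <- character(n_v)
  gt <- matrix("0/0", n_v, n_all)
  dosage <- matrix(0L, n_v, n_all)
  dp <- matrix(as.character(11L + stats::rpois(n_v * n_all, cfg$dp_lambda)),
               n_v, n_all)
  gq <- matrix(as.character(sample(seq(cfg$gq_range[1], cfg$gq_range[2]),
                                   n_v * n_all, replace = TRUE)),
               n_v, n_all)
  for (i in seq_len(n_v)) {
    rb <- seqs[[vp$chrom]][pos[i]]
    g <- stats::rbinom(n_all, 2, 0.4)
    g[n_all] <- 0L  # outgroup
    gt[i, ] <- c("0/0", "0/1", "1/1")[g + 1L]
    dosage[i, ] <- g
    ref[i] <- rb
    alt[i] <- sample(setdiff(bases, rb), 1)
    target <- (i - 1L) %% length(samples) + 1L
    if (type[i] == "dp_low") dp[i, target] <- "10"       # not > 10
    if (type[i] == "gq_low") gq[i, target] <- "20"       # not > 20
    if (type[i] == "missing") {
      gt[i, target] <- "./."; dp[i, target] <- "."; gq[i, target] <- "."
      dosage[i, target] <- NA_integer_
    }
    if (type[i] == "multiallelic") {
      alt[i] <- paste(sample(setdiff(bases, rb), 2), collapse = ",")
      gt[i, target] <- "1/2"
      dosage[i, target] <- NA_integer_
    }
    if (type[i] == "indel") {
      ref[i] <- paste0(rb, seqs[[vp$chrom]][pos[i] + 1L])
      alt[i] <- substr(ref[i], 1, 1)
    }
  }
  list(sites = data.frame(chrom = vp$chrom, pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE),
       gt = gt, dp = dp, gq = gq, dosage = dosage)
}

# Minimal deterministic GFF3 writer for the synthetic gene models.
write_sim_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(unlist(m$exons))
    lines <- c(lines,
               paste(m$chrom, "otterpg_sim", "gene", span[1], span[2], ".",
                     m$strand, ".", sprintf("ID=%s", m$id), sep = "\t"),
               paste(m$chrom, "otterpg_sim", "mRNA", span[1], span[2], ".",
                     m$strand, ".", sprintf("ID=%s.t1;Parent=%s", m$id, m$id),
                     sep = "\t"))
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    # phase: bases to skip at the start of each CDS piece, 5' to 3'
    if (m$strand == "+") {
      lens <- ex$end - ex$start + 1
      phases <- c(0, cumsum(lens)[-nrow(ex)]) %% 3
      phases <- (3 - phases) %% 3
    } else {
      ex2 <- ex[order(ex$start, decreasing = TRUE), , drop = FALSE]
      lens <- ex2$end - ex2$start + 1
      ph <- (3 - c(0, cumsum(lens)[-nrow(ex2)]) %% 3) %% 3
      phases <- ph[match(ex$start, ex2$start)]
    }
    for (i in seq_len(nrow(ex)))
      lines <- c(lines,
                 paste(m$chrom, "otterpg_sim", "CDS", ex$start[i], ex$end[i],
                       ".", m$strand, phases[i],
                       sprintf("ID=%s.t1.cds%d;Parent=%s.t1", m$id, i, m$id),
                       sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
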