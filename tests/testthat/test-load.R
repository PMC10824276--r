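# hand-worked toy genes -------------------------------------------------
# plus strand, single exon at c2:11-25, coding ATG GAA TAC GGT TAA
plus_reference <- function() {
  c2 <- paste0("AAAAAAAAAA", "ATGGAATACGGTTAA",
               paste(rep("A", 25), collapse = ""))
  Biostrings::DNAStringSet(c(c2 = c2))
}
plus_tx <- list(list(id = "tx_plus", chrom = "c2", strand = "+",
                     cds = data.frame(start = 11L, end = 25L)))

# minus strand, two exons; coding sequence ATG GCT TAT TAA lives on the
# reverse strand: genomic 21-26 = revcomp(TATTAA), 37-42 = revcomp(ATGGCT)
minus_reference <- function() {
  s <- rep("G", 100)
  s[21:26] <- strsplit("TTAATA", "")[[1]]
  s[37:42] <- strsplit("AGCCAT", "")[[1]]
  Biostrings::DNAStringSet(c(c1 = paste(s, collapse = "")))
}
minus_tx <- list(list(id = "tx_minus", chrom = "c1", strand = "-",
                      cds = data.frame(start = c(37L, 21L),
                                       end = c(42L, 26L))))

test_that("plus-strand codon changes are classified from the genetic code", {
  vt <- make_vt(matrix(1L, 3, 2), chrom = "c2", pos = c(16L, 19L, 20L),
                ref = c("A", "C", "G"), alt = c("G", "A", "C"))
  eff <- annotate_effects(vt, plus_tx, plus_reference())
  expect_equal(nrow(eff), 3L)
  # GAA -> GAG: Glu -> Glu, synonymous
  expect_equal(eff$category[1], "synonymous")
  expect_equal(eff$ref_codon[1], "GAA")
  expect_equal(eff$alt_codon[1], "GAG")
  # TAC -> TAA: Tyr -> stop
  expect_equal(eff$category[2], "stop_gain")
  expect_equal(eff$alt_aa[2], "*")
  # GGT -> CGT: Gly -> Arg, Grantham 125, radical
  expect_equal(eff$category[3], "nonsynonymous")
  expect_equal(eff$grantham[3], grantham_score("G", "R"))
  expect_equal(eff$grantham_class[3], "radical")
  # a site outside every CDS yields no call
  vt_out <- make_vt(matrix(1L, 1, 2), chrom = "c2", pos = 5L,
                    ref = "A", alt = "G")
  expect_equal(nrow(annotate_effects(vt_out, plus_tx, plus_reference())), 0L)
  # reference-mismatch sites are skipped with a warning
  vt_bad <- make_vt(matrix(1L, 1, 2), chrom = "c2", pos = 16L,
                    ref = "C", alt = "G")
  expect_warning(out <- annotate_effects(vt_bad, plus_tx, plus_reference()),
                 "mismatch")
  expect_equal(nrow(out), 0L)
})

test_that("minus-strand codons are reverse-complemented correctly", {
  # hand-worked: genomic C>T at 39 hits codon 2 position 1 (GCT -> ACT,
  # Ala -> Thr); genomic A>T at 24 hits codon 3 position 3 (TAT -> TAA,
  # stop gain); genomic T>A at 22 hits the terminal stop (TAA -> TTA,
  # stop loss)
  vt <- make_vt(matrix(1L, 3, 2), chrom = "c1", pos = c(22L, 24L, 39L),
                ref = c("T", "A", "C"), alt = c("A", "T", "T"))
  eff <- annotate_effects(vt, minus_tx, minus_reference())
  eff <- eff[order(eff$pos), ]
  expect_equal(eff$category, c("stop_loss", "stop_gain", "nonsynonymous"))
  expect_equal(eff$ref_codon, c("TAA", "TAT", "GCT"))
  expect_equal(eff$alt_codon, c("TTA", "TAA", "ACT"))
  expect_equal(eff$grantham[3], grantham_score("A", "T"))
  expect_equal(eff$codon_index, c(4L, 3L, 2L))
})

test_that("annotating a mirrored gene yields identical amino-acid calls", {
  ref <- plus_reference()
  L <- Biostrings::width(ref)[[1]]
  mirrored <- Biostrings::reverseComplement(ref)
  names(mirrored) <- "c2"
  comp <- function(x) chartr("ACGT", "TGCA", x)
  pos <- c(16L, 19L, 20L)
  refs <- c("A", "C", "G"); alts <- c("G", "A", "C")
  vt <- make_vt(matrix(1L, 3, 2), chrom = "c2", pos = pos,
                ref = refs, alt = alts)
  mpos <- L - pos + 1L
  ord <- order(mpos)
  vt_m <- make_vt(matrix(1L, 3, 2), chrom = "c2", pos = mpos[ord],
                  ref = comp(refs)[ord], alt = comp(alts)[ord])
  tx_m <- list(list(id = "tx_mirror", chrom = "c2", strand = "-",
                    cds = data.frame(start = L - 25L + 1L,
                                     end = L - 11L + 1L)))
  eff <- annotate_effects(vt, plus_tx, ref)
  eff_m <- annotate_effects(vt_m, tx_m, mirrored)
  eff_m <- eff_m[order(match(L - eff_m$pos + 1L, eff$pos)), ]
  expect_equal(eff_m$ref_aa, eff$ref_aa)
  expect_equal(eff_m$alt_aa, eff$alt_aa)
  expect_equal(eff_m$category, eff$category)
  expect_equal(eff_m$codon_index, eff$codon_index)
})

test_that("GFF3 transcripts are read with strand-aware CDS order", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t21\t42\t.\t-\t.\tID=g1",
               "c1\tsrc\tmRNA\t21\t42\t.\t-\t.\tID=g1.t1;Parent=g1",
               "c1\tsrc\tCDS\t21\t26\t.\t-\t0\tID=c.1;Parent=g1.t1",
               "c1\tsrc\tCDS\t37\t42\t.\t-\t0\tID=c.2;Parent=g1.t1",
               "c1\tsrc\tmRNA\t50\t57\t.\t+\t.\tID=g2.t1",
               "c1\tsrc\tCDS\t50\t57\t.\t+\t0\tID=c.3;Parent=g2.t1"),
             path)
  expect_warning(tx <- read_transcripts(path), "multiple of 3")
  expect_equal(names(tx), "g1.t1")
  expect_equal(tx$g1.t1$strand, "-")
  # minus strand: 5'-most CDS (highest coordinate) listed first
  expect_equal(tx$g1.t1$cds$start, c(37L, 21L))
  unlink(path)
})

test_that("outgroup polarization follows the homozygosity rule", {
  geno <- matrix(c(0L, 2L, 1L, NA), 4, 1)
  vt <- make_vt(cbind(geno, c(0L, 1L, 2L, 1L)), samples = c("out", "s1"))
  anc <- polarize_alleles(vt, "out")
  expect_equal(anc, c("ref", "alt", "unclassified", "unclassified"))
  expect_error(polarize_alleles(vt, "nope"), "nope")
})

test_that("per-genome load recovers a planted bookkeeping fixture", {
  # 10 derived synonymous + 4 derived nonsynonymous (Grantham 30, 60,
  # 110, 120) + outgroup-het and outgroup-missing sites that must drop out
  n <- 16L
  pos <- seq_len(n) * 10L
  cats <- c(rep("synonymous", 10), rep("nonsynonymous", 4),
            "synonymous", "nonsynonymous")
  scores <- c(rep(NA, 10), 30, 60, 110, 120, NA, 200)
  effects <- data.frame(chrom = "chr1", pos = pos, category = cats,
                        grantham = scores, stringsAsFactors = FALSE)
  out_geno <- c(rep(0L, 14), 1L, NA)   # last two sites unclassified
  s1 <- rep(1L, n)                     # carries derived everywhere
  s2 <- rep(0L, n)                     # homozygous ancestral everywhere
  vt <- make_vt(cbind(s1, s2, out_geno), pos = pos,
                samples = c("s1", "s2", "out"))
  vt$geno[is.na(vt$geno)] <- NA        # keep NA for the outgroup only
  pop <- population_map(c("s1", "s2"), c("A", "A"), outgroup = "out")
  ld <- per_genome_load(vt, effects, pop)
  r1 <- ld[ld$sample == "s1", ]
  expect_equal(r1$n_syn, 10)
  expect_equal(r1$n_nonsyn, 4)
  expect_equal(r1$n_lof, 0)
  expect_equal(r1$ratio_ns_s, 0.4)
  expect_equal(r1$mean_grantham, mean(c(30, 60, 110, 120)))
  expect_equal(r1$sum_grantham_deleterious, 60 + 110 + 120)
  expect_equal(r1$mean_grantham_deleterious, mean(c(60, 110, 120)))
  r2 <- ld[ld$sample == "s2", ]
  expect_equal(r2$n_syn + r2$n_nonsyn + r2$n_lof, 0)
  expect_true(is.na(r2$ratio_ns_s))
})

test_that("copy counting weighs homozygotes twice; carrier counts once", {
  effects <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                        category = "synonymous", grantham = NA_integer_,
                        stringsAsFactors = FALSE)
  vt <- make_vt(cbind(c(1L, 2L), c(0L, 0L)), pos = c(10L, 20L),
                samples = c("s1", "out"))
  pop <- population_map("s1", "A", outgroup = "out")
  expect_equal(per_genome_load(vt, effects, pop, mode = "carrier")$n_syn, 2)
  expect_equal(per_genome_load(vt, effects, pop, mode = "copies")$n_syn, 3)
})

test_that("unclassified exclusion never increases any count", {
  set.seed(903)
  n <- 30L
  geno <- matrix(sample(0:2, n * 4, TRUE), n, 4)
  out_all <- rep(0L, n)
  out_some <- out_all
  out_some[sample(n, 10)] <- 1L
  effects <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                        category = sample(c("synonymous", "nonsynonymous",
                                            "stop_gain"), n, TRUE),
                        grantham = NA_integer_, stringsAsFactors = FALSE)
  effects$grantham[effects$category == "nonsynonymous"] <-
    sample(c(30L, 80L, 120L),
           sum(effects$category == "nonsynonymous"), TRUE)
  pop <- population_map(paste0("s", 1:4), rep("A", 4), outgroup = "out")
  mk <- function(out_g) {
    vt <- make_vt(cbind(geno, out_g), pos = seq_len(n) * 10L,
                  samples = c(paste0("s", 1:4), "out"))
    per_genome_load(vt, effects, pop)
  }
  full <- mk(out_all)
  part <- mk(out_some)
  for (col in c("n_syn", "n_nonsyn", "n_lof", "sum_grantham_deleterious"))
    expect_true(all(part[[col]] <= full[[col]]))
})

test_that("cohort effect calls partition into the four categories", {
  co <- cohort_default()
  tx <- read_transcripts(co$truth$files$gff)
  eff <- annotate_effects(co$auto, tx, co$truth$files$fasta)
  expect_true(all(eff$category %in% c("synonymous", "nonsynonymous",
                                      "stop_gain", "stop_loss")))
  expect_true(all(eff$ref_aa[eff$category == "synonymous"] ==
                    eff$alt_aa[eff$category == "synonymous"]))
  expect_true(all(eff$alt_aa[eff$category == "stop_gain"] == "*"))
  expect_true(all(eff$ref_aa[eff$category == "stop_loss"] == "*"))
  expect_true(all(is.na(eff$grantham) ==
                    (eff$category != "nonsynonymous")))
  .cohorts$effects <- eff
})
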