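#' Read protein-coding transcript models from a GFF3 file
#'
#' Imports CDS features and groups them into transcripts by their
#' `Parent` attribute (falling back to `ID` when absent). CDS intervals
#' are ordered 5' to 3' on the coding strand. Transcripts whose CDS
#' length is not a multiple of 3 are dropped with a warning, since their
#' reading frame cannot be reconstructed from the annotation alone.
#'
#' @param path GFF3 file
#' @return list of transcript models, each a list with `id`, `chrom`,
#'   `strand` (`"+"`/`"-"`) and `cds` (data.frame of 1-based inclusive
#'   `start`, `end`, ordered 5' to 3')
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(df)) stop("no CDS features in ", path)
  parent <- if ("Parent" %in% names(df))
    vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  else rep(NA_character_, nrow(df))
  id <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  tx_id <- ifelse(is.na(parent) | !nzchar(parent), id, parent)
  out <- list()
  for (tx in unique(tx_id)) {
    rows <- df[tx_id == tx, , drop = FALSE]
    strand <- as.character(rows$strand[1])
    cds <- data.frame(start = rows$start, end = rows$end)
    cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(cds) <- NULL
    if (sum(cds$end - cds$start + 1) %% 3 != 0) {
      warning("transcript ", tx, " CDS length is not a multiple of 3; skipped")
      next
    }
    out[[tx]] <- list(id = tx, chrom = as.character(rows$seqnames[1]),
                      strand = strand, cds = cds)
  }
  if (!length(out)) stop("no usable transcripts in ", path)
  out
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Map genomic positions to 1-based positions along the spliced CDS of one
# transcript; NA for positions outside the CDS.
cds_position <- function(tx, pos) {
  off <- 0L
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(tx$cds))) {
    s <- tx$cds$start[i]; e <- tx$cds$end[i]
    inside <- pos >= s & pos <= e
    out[inside] <- off + if (tx$strand == "+") pos[inside] - s + 1L else
      e - pos[inside] + 1L
    off <- off + (e - s + 1L)
  }
  out
}

# Spliced CDS sequence (coding strand) of one transcript as a character
# string, given a named list/DNAStringSet of chromosome sequences.
cds_sequence <- function(tx, reference) {
  chrom_seq <- as.character(reference[[tx$chrom]])
  pieces <- substring(chrom_seq, pmin(tx$cds$start, tx$cds$end),
                      pmax(tx$cds$start, tx$cds$end))
  if (tx$strand == "-") {
    pieces <- vapply(pieces, function(p)
      paste(rev(strsplit(complement_base(p), "")[[1]]), collapse = ""), "")
  }
  paste(pieces, collapse = "")
}

severity_rank <- c(synonymous = 1, nonsynonymous = 2, stop_loss = 3,
                   stop_gain = 4)

#' Annotate coding consequences of SNPs
#'
#' For every biallelic SNP falling inside the CDS of a transcript,
#' reconstructs the affected codon (respecting strand: alleles are
#' complemented and codons read 5' to 3' on the coding strand),
#' translates reference and alternate codons with the standard genetic
#' code, and classifies the change as `synonymous`, `nonsynonymous`,
#' `stop_gain` or `stop_loss`. Nonsynonymous calls carry the Grantham
#' score and its conservative/moderate/radical class. Sites whose VCF
#' reference allele disagrees with the reference genome are skipped with
#' a warning. Sites outside every CDS produce no call.
#'
#' @param vt a `variant_table`
#' @param transcripts output of [read_transcripts()]
#' @param reference a `Biostrings::DNAStringSet` of chromosome sequences
#'   (or a FASTA path)
#' @return data.frame with one row per (site, overlapping transcript):
#'   `chrom`, `pos`, `ref`, `alt`, `transcript`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `category`,
#'   `grantham`, `grantham_class`
#' @export
annotate_effects <- function(vt, transcripts, reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub(" .*", "", names(reference))
  code <- Biostrings::GENETIC_CODE
  snp <- which(vt$sites$is_snp & vt$sites$is_biallelic)
  rows <- list()
  for (tx in transcripts) {
    on_chr <- snp[vt$sites$chrom[snp] == tx$chrom]
    if (!length(on_chr)) next
    cpos <- cds_position(tx, vt$sites$pos[on_chr])
    hit <- on_chr[!is.na(cpos)]
    if (!length(hit)) next
    cpos <- cpos[!is.na(cpos)]
    cds_seq <- cds_sequence(tx, reference)
    chrom_seq <- as.character(reference[[tx$chrom]])
    for (j in seq_along(hit)) {
      i <- hit[j]
      pos <- vt$sites$pos[i]
      ref_al <- vt$sites$ref[i]; alt_al <- vt$sites$alt[i]
      if (substring(chrom_seq, pos, pos) != ref_al) {
        warning("reference mismatch at ", tx$chrom, ":", pos, "; site skipped")
        next
      }
      ci <- (cpos[j] - 1L) %/% 3L + 1L
      within <- (cpos[j] - 1L) %% 3L + 1L
      ref_codon <- substring(cds_seq, 3 * (ci - 1) + 1, 3 * ci)
      alt_coding <- if (tx$strand == "+") alt_al else complement_base(alt_al)
      alt_codon <- ref_codon
      substring(alt_codon, within, within) <- alt_coding
      ref_aa <- code[[ref_codon]]
      alt_aa <- code[[alt_codon]]
      category <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gain"
      else if (ref_aa == "*") "stop_loss"
      else "nonsynonymous"
      gs <- if (category == "nonsynonymous")
        grantham_score(ref_aa, alt_aa) else NA_integer_
      rows[[length(rows) + 1]] <- data.frame(
        chrom = tx$chrom, pos = pos, ref = ref_al, alt = alt_al,
        transcript = tx$id, codon_index = ci,
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa, category = category,
        grantham = gs,
        grantham_class = if (is.na(gs)) NA_character_ else
          grantham_classify(gs),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      transcript = character(0), codon_index = integer(0),
                      ref_codon = character(0), alt_codon = character(0),
                      ref_aa = character(0), alt_aa = character(0),
                      category = character(0), grantham = integer(0),
                      grantham_class = character(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Collapse per-transcript effect calls to one call per site
#'
#' Sites overlapped by several transcripts keep the most severe call
#' (stop gain > stop loss > nonsynonymous > synonymous); ties keep the
#' first transcript encountered.
#'
#' @param effects data.frame from [annotate_effects()]
#' @return data.frame with one row per site
#' @export
collapse_effects <- function(effects) {
  if (!nrow(effects)) return(effects)
  key <- paste(effects$chrom, effects$pos)
  sev <- severity_rank[effects$category]
  ord <- order(key, -sev)
  eff <- effects[ord, , drop = FALSE]
  out <- eff[!duplicated(paste(eff$chrom, eff$pos)), , drop = FALSE]
  out <- out[order(match(paste(out$chrom, out$pos), unique(key))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
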