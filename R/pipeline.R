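#' Pipeline configuration
#'
#' Bundles the input paths, stage toggles and per-stage parameter blocks
#' for [run_pipeline()]. Any field can be overridden; unspecified
#' parameters keep the package defaults.
#'
#' @param vcf,pops,genome required input paths (multi-sample VCF,
#'   sample-to-population TSV, genome-model TSV)
#' @param gff,fasta coding annotation and reference sequence, required
#'   only when the load stage is enabled
#' @param outgroup outgroup sample name (required for the load stage and
#'   for unfolded spectra)
#' @param out_dir output directory
#' @param stages character vector of stages to run, a subset of
#'   `c("filter", "diversity", "prune", "pca", "roh", "load", "stats")`;
#'   stages always execute in that order
#' @param filter_params,prune_params,roh_params,load_params,sfs_params
#'   named lists overriding stage parameters: `filter_params` feeds
#'   [filter_sites()], `prune_params` [prune_config()], `roh_params`
#'   [roh_params()], `load_params` accepts `mode` for
#'   [per_genome_load()], `sfs_params` accepts `project_to` and `folded`
#'   for [sfs()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(vcf, pops, genome, gff = NULL, fasta = NULL,
                            outgroup = NULL, out_dir = "otterpg_out",
                            stages = c("filter", "diversity", "prune",
                                       "pca", "roh", "load", "stats"),
                            filter_params = list(), prune_params = list(),
                            roh_params = list(), load_params = list(),
                            sfs_params = list()) {
  known <- c("filter", "diversity", "prune", "pca", "roh", "load", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("load" %in% stages && (is.null(gff) || is.null(fasta) ||
                             is.null(outgroup)))
    stop("the load stage requires gff, fasta and outgroup")
  structure(list(vcf = vcf, pops = pops, genome = genome, gff = gff,
                 fasta = fasta, outgroup = outgroup, out_dir = out_dir,
                 stages = known[known %in% stages],
                 filter_params = filter_params,
                 prune_params = prune_params, roh_params = roh_params,
                 load_params = load_params, sfs_params = sfs_params),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 12, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order -- site filtering,
#' diversity statistics (heterozygosity, pi, d_xy, d_a, folded or
#' polarized site frequency spectra), SNP thinning, PCA, ROH detection
#' with F_ROH summaries, coding-variant mutation load, and group
#' comparisons -- handing results between stages as plain files under
#' `out_dir` so any stage can be re-run and inspected independently.
#' A JSON manifest records the produced files and the parameters used;
#' re-running with unchanged inputs reproduces identical outputs. Any
#' stage failure aborts with the stage name; files already produced stay
#' on disk and the manifest is written with `complete = FALSE`.
#'
#' @param config a [pipeline_config()]
#' @return invisible manifest (list with `files`, `parameters`,
#'   `complete`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(files = list(), parameters = list(), complete = FALSE)
  emit <- function(stage, name, path) {
    manifest$files[[length(manifest$files) + 1]] <<-
      list(stage = stage, name = name, file = basename(path))
  }
  finish <- function() {
    path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    manifest
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      finish()
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  genome <- read_genome_model(config$genome)
  pop <- read_population_map(config$pops, outgroup = config$outgroup)
  vt_raw <- read_vcf(config$vcf)

  st <- config$stages
  vt <- vt_raw
  if ("filter" %in% st) {
    run_stage("filter", {
      vt <- do.call(filter_sites, c(list(vt_raw), config$filter_params))
      manifest$parameters$filter <- config$filter_params
      write_vcf(vt, out("filtered.vcf"))
      write_filter_report(vt, out("filter_report.tsv"))
      emit("filter", "filtered_vcf", out("filtered.vcf"))
      emit("filter", "filter_report", out("filter_report.tsv"))
    })
  }
  vt_auto <- select_autosomes(vt, genome)

  if ("diversity" %in% st) {
    run_stage("diversity", {
      ingroup <- pop$assignments$sample[!is.na(pop$assignments$population)]
      het <- heterozygosity(subset_samples(vt_auto, ingroup), genome)
      het_df <- data.frame(sample = names(het),
                           population = pop$assignments$population[
                             match(names(het), pop$assignments$sample)],
                           heterozygosity = as.numeric(het))
      write_tsv(het_df, out("heterozygosity.tsv"))
      div <- divergence_summary(vt_auto, pop, genome)
      write_tsv(data.frame(population = names(div$pi),
                           pi = as.numeric(div$pi)),
                out("population_pi.tsv"))
      write_tsv(div$pairs, out("divergence.tsv"))
      emit("diversity", "heterozygosity", out("heterozygosity.tsv"))
      emit("diversity", "population_pi", out("population_pi.tsv"))
      emit("diversity", "divergence", out("divergence.tsv"))
      sp <- config$sfs_params
      folded <- isTRUE(sp$folded) || is.null(config$outgroup)
      for (p in population_labels(pop)) {
        s <- sfs(vt_auto, pop, p, project_to = sp$project_to,
                 folded = folded,
                 outgroup = if (!folded) config$outgroup)
        f <- out(sprintf("sfs_%s.txt", p))
        export_sfs(s, f)
        emit("diversity", sprintf("sfs_%s", p), f)
      }
    })
  }

  vt_pruned <- NULL
  if ("prune" %in% st) {
    run_stage("prune", {
      cfg <- do.call(prune_config, config$prune_params)
      manifest$parameters$prune <- unclass(cfg)
      ingroup <- pop$assignments$sample[!is.na(pop$assignments$population)]
      vt_pruned <- prune_variants(subset_samples(vt_auto, ingroup), cfg)
      write_vcf(vt_pruned, out("pruned.vcf"))
      export_structure_input(vt_pruned, out("structure_input.tsv"))
      emit("prune", "pruned_vcf", out("pruned.vcf"))
      emit("prune", "structure_input", out("structure_input.tsv"))
    })
  }
  if ("pca" %in% st) {
    run_stage("pca", {
      if (is.null(vt_pruned)) {
        ingroup <- pop$assignments$sample[!is.na(pop$assignments$population)]
        vt_pruned <- subset_samples(vt_auto, ingroup)
      }
      pc <- pca_genotypes(vt_pruned)
      write_pca(pc, out("pca_scores.tsv"))
      emit("pca", "pca_scores", out("pca_scores.tsv"))
    })
  }

  roh_summary <- NULL
  if ("roh" %in% st) {
    run_stage("roh", {
      rp <- do.call(roh_params, config$roh_params)
      manifest$parameters$roh <- unclass(rp)
      ingroup <- pop$assignments$sample[!is.na(pop$assignments$population)]
      segs <- detect_roh(subset_samples(vt_auto, ingroup), rp)
      roh_summary <- summarize_roh(segs, genome, samples = ingroup)
      write_tsv(segs, out("roh_segments.tsv"))
      write_tsv(roh_summary, out("roh_summary.tsv"))
      emit("roh", "roh_segments", out("roh_segments.tsv"))
      emit("roh", "roh_summary", out("roh_summary.tsv"))
    })
  }

  load_df <- NULL
  if ("load" %in% st) {
    run_stage("load", {
      tx <- read_transcripts(config$gff)
      ref <- Biostrings::readDNAStringSet(config$fasta)
      eff <- annotate_effects(vt_auto, tx, ref)
      eff1 <- collapse_effects(eff)
      mode <- if (!is.null(config$load_params$mode))
        config$load_params$mode else "carrier"
      manifest$parameters$load <- list(mode = mode,
                                       outgroup = config$outgroup)
      load_df <- per_genome_load(vt_auto, eff1, pop, mode = mode)
      write_tsv(eff, out("effects.tsv"))
      write_tsv(load_df, out("load_summary.tsv"))
      write_tsv(summarize_load_by_population(load_df),
                out("load_by_population.tsv"))
      emit("load", "effects", out("effects.tsv"))
      emit("load", "load_summary", out("load_summary.tsv"))
      emit("load", "load_by_population", out("load_by_population.tsv"))
    })
  }

  if ("stats" %in% st) {
    run_stage("stats", {
      rows <- list()
      add_comparison <- function(df, value) {
        tk <- compare_groups(df, value)
        rows[[length(rows) + 1]] <<-
          cbind(statistic = value,
                data.frame(F = tk$anova$F, p = tk$anova$p,
                           df1 = tk$anova$df1, df2 = tk$anova$df2),
                row.names = NULL)
        cbind(statistic = value, tk$pairs, row.names = NULL)
      }
      pairs_out <- list()
      if ("diversity" %in% st) {
        het_df <- utils::read.table(out("heterozygosity.tsv"), header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
        pairs_out[[length(pairs_out) + 1]] <-
          add_comparison(het_df, "heterozygosity")
      }
      if (!is.null(roh_summary))
        pairs_out[[length(pairs_out) + 1]] <- add_comparison(
          cbind(roh_summary,
                population = pop$assignments$population[
                  match(roh_summary$sample, pop$assignments$sample)]),
          "f_roh")
      if (!is.null(load_df)) {
        for (v in c("n_nonsyn", "ratio_ns_s", "sum_grantham_deleterious"))
          pairs_out[[length(pairs_out) + 1]] <- add_comparison(load_df, v)
      }
      if (length(rows)) {
        write_tsv(do.call(rbind, rows), out("group_anova.tsv"))
        write_tsv(do.call(rbind, pairs_out), out("group_tukey.tsv"))
        emit("stats", "group_anova", out("group_anova.tsv"))
        emit("stats", "group_tukey", out("group_tukey.tsv"))
      }
    })
  }

  manifest$complete <- TRUE
  invisible(finish())
}
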