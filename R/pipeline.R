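# Pipeline orchestration: one entry point running the stages on files in an
# output directory, with deterministic seeding, a provenance manifest and a
# line-delimited log.

#' Pipeline run configuration
#'
#' Collects every tunable threshold with its default: pathologist-purity
#' tolerance 0.15, cancer-chromosome-fraction cutoffs 0.85 (0.63 for ATRX),
#' loess span 0.5, 1000 MAE bootstraps, CI threshold 0.2, plus the
#' simulation settings ([sim_config()]) and the global seed.
#'
#' @param seed Global seed; per-stage seeds are fanned out by stable
#'   hashing of the stage name.
#' @param outdir Output/working directory.
#' @param purity_tolerance,ccf_cutoff,ccf_cutoff_atrx,loess_span,n_boot,ci_threshold,n_max
#'   Stage thresholds; every default is overridable.
#' @param sim A [sim_config()] for the simulate stage.
#' @param ... Overrides stored alongside (reserved).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("panetsig_run_"),
                       purity_tolerance = 0.15, ccf_cutoff = 0.85,
                       ccf_cutoff_atrx = 0.63, loess_span = 0.5,
                       n_boot = 1000, ci_threshold = 0.2, n_max = 8,
                       sim = NULL, ...) {
  if (purity_tolerance < 0 || ccf_cutoff <= 0 || ccf_cutoff > 1 ||
      loess_span <= 0 || ci_threshold < 0 || ci_threshold > 1) {
    abort("invalid threshold in run_config")
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), outdir = outdir,
         purity_tolerance = purity_tolerance, ccf_cutoff = ccf_cutoff,
         ccf_cutoff_atrx = ccf_cutoff_atrx, loess_span = loess_span,
         n_boot = n_boot, ci_threshold = ci_threshold, n_max = n_max,
         sim = sim, extra = list(...)),
    class = "run_config"
  )
}

pipeline_stages <- c("simulate", "cnstate", "timing", "mae", "skew",
                     "expression", "chip", "meta")

log_line <- function(config, stage, msg, n = NA) {
  line <- sprintf("stage=%s n=%s %s", stage,
                  ifelse(is.na(n), "-", as.character(n)), msg)
  cat(line, "\n", file = file.path(config$outdir, "pipeline.log"),
      append = TRUE)
  invisible(line)
}

out_path <- function(config, ...) file.path(config$outdir, ...)

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`: simulate followed by every analysis
#' stage on the simulated cohort) against the files in `config$outdir`,
#' writing TSV/JSON results, a `pipeline.log`, and a deterministic
#' provenance manifest (`manifest.json`: package version, seed, config
#' hash, per-stage record counts). Identical seeds and configs yield
#' identical manifests and outputs.
#'
#' @param subcommand One of `"simulate"`, `"cnstate"`, `"timing"`,
#'   `"mae"`, `"skew"`, `"expression"`, `"chip"`, `"meta"`, `"all"`.
#' @param config A [run_config()].
#' @return Named list of the stage results, invisibly.
#' @export
run_pipeline <- function(subcommand = "all", config = run_config()) {
  if (!subcommand %in% c(pipeline_stages, "all")) {
    abort(sprintf("unknown subcommand '%s'", subcommand))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (config$n_boot < 1000) {
    warn(sprintf("n_boot = %d is below the standard 1000 bootstraps",
                 config$n_boot))
  }
  stages <- if (subcommand == "all") pipeline_stages else subcommand
  counts <- list()
  results <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- switch(
      st,
      simulate = stage_simulate(config),
      cnstate = stage_cnstate(config),
      timing = stage_timing(config),
      mae = stage_mae(config),
      skew = stage_skew(config),
      expression = stage_expression(config),
      chip = stage_chip(config),
      meta = stage_meta(config)
    )
    counts[[st]] <- res$n
    results[[st]] <- res$value
    log_line(config, st,
             sprintf("elapsed=%.2fs", proc.time()[["elapsed"]] - t0),
             n = res$n)
  }
  manifest <- list(
    package = "panetsig",
    version = as.character(utils::packageVersion("panetsig")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    stages = stages,
    records = counts
  )
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

stage_simulate <- function(config) {
  cohort <- simulate_cohort(config$sim)
  bands <- synthetic_cytobands()
  arms <- chromosome_arms(bands)
  readr::write_tsv(bands, out_path(config, "cytobands.tsv"),
                   col_names = FALSE)
  write_segments(cohort$segments, out_path(config, "truth_segments.tsv"))
  write_mutations(cohort$mutations, out_path(config, "mutations.tsv"))
  readr::write_tsv(cohort$meta, out_path(config, "samples.tsv"))
  set.seed(child_seed(config$sim$seed, "bins"))
  bins <- purrr::map(unique(cohort$meta$sample_id), function(id) {
    simulate_binned_counts(
      cohort$segments %>% filter(.data$sample_id == id),
      purity = cohort$meta$purity[cohort$meta$sample_id == id],
      config$sim
    )
  }) %>% bind_rows()
  write_binned_counts(bins, out_path(config, "binned_counts.tsv"))
  ex <- simulate_expression(config$sim, arms)
  write_expression(ex$expr, ex$genes, out_path(config, "expression.tsv"),
                   out_path(config, "genes.bed"))
  readr::write_tsv(ex$genes, out_path(config, "genes_truth.tsv"))
  snps <- simulate_rna_snps(config$sim)
  readr::write_tsv(snps, out_path(config, "rna_snps.tsv"))
  trio <- simulate_trio(config$sim)
  readr::write_tsv(trio$snps, out_path(config, "trio_snps.tsv"))
  readr::write_tsv(trio$truth, out_path(config, "trio_truth.tsv"))
  cgh <- simulate_cgh_cohort(config$sim)
  readr::write_tsv(cgh$profiles, out_path(config, "cgh_profiles.tsv"))
  readr::write_tsv(cgh$meta, out_path(config, "cgh_samples.tsv"))
  readr::write_csv(cgh$tables, out_path(config, "cgh_tables.csv"))
  ctl_cfg <- config$sim
  ctl_cfg$seed <- child_seed(config$sim$seed, "control_peaks")
  write_peaks(simulate_peaks(config$sim, arms, pericen_fraction = 0.6),
              out_path(config, "peaks_depleted.bed"))
  write_peaks(simulate_peaks(ctl_cfg, arms, n_peaks = 350,
                             pericen_fraction = 0.3),
              out_path(config, "peaks_control.bed"))
  list(n = nrow(cohort$meta), value = cohort)
}

stage_cnstate <- function(config) {
  bins <- read_binned_counts(out_path(config, "binned_counts.tsv"))
  meta <- readr::read_tsv(out_path(config, "samples.tsv"),
                          show_col_types = FALSE)
  seg <- purrr::map(unique(meta$sample_id), function(id) {
    call_chromosome_states(
      bins %>% filter(.data$sample_id == id),
      purity = meta$purity[meta$sample_id == id],
      germline_het_density = config$sim$het_snps_per_bin
    )
  }) %>% bind_rows()
  write_segments(seg, out_path(config, "called_segments.tsv"))
  pos_ids <- meta$sample_id[meta$mad_status == "MAD+"]
  motif <- cohort_motif(seg %>% filter(.data$sample_id %in% pos_ids))
  readr::write_tsv(motif, out_path(config, "motif_madpos.tsv"))
  cooc <- signature_cooccurrence(seg)
  readr::write_tsv(cooc, out_path(config, "cooccurrence.tsv"))
  per_sample <- seg %>%
    group_by(.data$sample_id) %>%
    dplyr::group_split() %>%
    purrr::map(function(df) {
      tibble(sample_id = df$sample_id[1],
             scarpa_group = classify_scarpa_group(df),
             ci = ci_stratum(df, config$ci_threshold))
    }) %>% bind_rows()
  readr::write_tsv(per_sample, out_path(config, "sample_groups.tsv"))
  list(n = nrow(seg), value = list(segments = seg, motif = motif,
                                   cooccurrence = cooc,
                                   groups = per_sample))
}

stage_timing <- function(config) {
  muts <- read_mutations(out_path(config, "mutations.tsv"))
  meta <- readr::read_tsv(out_path(config, "samples.tsv"),
                          show_col_types = FALSE)
  seg_path <- out_path(config, "called_segments.tsv")
  if (!file.exists(seg_path)) {
    seg_path <- out_path(config, "truth_segments.tsv")
  }
  segs <- read_segments(seg_path)
  calls <- select_copy_model(muts, meta, segments = segs,
                             n_max = config$n_max,
                             tolerance = config$purity_tolerance,
                             ccf_cutoff = config$ccf_cutoff)
  readr::write_tsv(calls, out_path(config, "timing_calls.tsv"))
  summ <- timing_summary(calls, cutoff = config$ccf_cutoff)
  enrich <- gene_enrichment(calls, cutoff = config$ccf_cutoff)
  k <- sum(summ$n_early[summ$cohort != "pooled"])
  n <- sum(summ$n_samples[summ$cohort != "pooled"])
  out <- list(
    summary = summ,
    early_binomial_p = if (n > 0) binomial_enrichment(k, n) else NA,
    gene_enrichment = enrich
  )
  jsonlite::write_json(out, out_path(config, "timing_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(n = nrow(calls), value = c(list(calls = calls), out))
}

stage_mae <- function(config) {
  snps <- readr::read_tsv(out_path(config, "rna_snps.tsv"),
                          show_col_types = FALSE)
  res <- mae_scan(snps, n_boot = config$n_boot,
                  seed = child_seed(config$seed, "mae"))
  readr::write_tsv(res, out_path(config, "mae_results.tsv"))
  list(n = nrow(res), value = res)
}

stage_skew <- function(config) {
  snps <- readr::read_tsv(out_path(config, "trio_snps.tsv"),
                          show_col_types = FALSE)
  truth <- readr::read_tsv(out_path(config, "trio_truth.tsv"),
                           show_col_types = FALSE)
  sk <- parental_skew(snps, loh_chromosomes = truth$chrom[truth$loh])
  readr::write_tsv(tidy(sk), out_path(config, "skew_chromosomes.tsv"))
  jsonlite::write_json(as.list(glance(sk)),
                       out_path(config, "skew_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(n = nrow(tidy(sk)), value = sk)
}

stage_expression <- function(config) {
  ex <- read_expression(out_path(config, "expression.tsv"),
                        out_path(config, "genes.bed"))
  meta <- readr::read_tsv(out_path(config, "samples.tsv"),
                          show_col_types = FALSE) %>%
    select("sample_id", "mad_status")
  arms <- chromosome_arms(synthetic_cytobands())
  z <- gene_zscores(ex$expr, meta)
  genes <- add_fractional_distance(ex$genes, arms)
  zg <- z %>% inner_join(genes, by = "gene")
  rc <- repression_curves(zg, span = config$loess_span,
                          loh_set = config$sim$loh_chromosomes,
                          het_set = config$sim$het_chromosomes)
  readr::write_tsv(tidy(rc), out_path(config, "repression_curves.tsv"))
  jsonlite::write_json(as.list(glance(rc)),
                       out_path(config, "repression_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(n = nrow(zg), value = rc)
}

stage_chip <- function(config) {
  bands <- synthetic_cytobands()
  depleted <- read_peaks(out_path(config, "peaks_depleted.bed"))
  control <- read_peaks(out_path(config, "peaks_control.bed"))
  classified <- classify_peaks(depleted, control)
  stats_d <- cytoband_peak_stats(depleted, bands,
                                 total_mapped_reads = 1e6)
  readr::write_tsv(classified, out_path(config, "peaks_classified.tsv"))
  readr::write_tsv(stats_d, out_path(config, "cytoband_peak_stats.tsv"))
  list(n = nrow(classified),
       value = list(classified = classified, stats = stats_d))
}

stage_meta <- function(config) {
  tables <- read_study_tables(out_path(config, "cgh_tables.csv"))
  profiles <- readr::read_tsv(out_path(config, "cgh_profiles.tsv"),
                              show_col_types = FALSE)
  res <- pooled_or(tables)
  cl <- cluster_profiles(profiles, k = 5)
  strata <- cgh_ci_stratum(profiles, threshold = config$ci_threshold)
  readr::write_tsv(tidy(res), out_path(config, "meta_per_study.tsv"))
  jsonlite::write_json(as.list(glance(res)),
                       out_path(config, "meta_pooled.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(cl, out_path(config, "cgh_clusters.tsv"))
  readr::write_tsv(strata, out_path(config, "cgh_ci_strata.tsv"))
  list(n = nrow(tables), value = list(pooled = res, clusters = cl,
                                      strata = strata))
}
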