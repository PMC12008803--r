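# End-to-end orchestration: process -> score -> classify -> sweep ->
# endogenous, with plain-TSV stage outputs and a reproducibility manifest.

#' Run the full screen analysis
#'
#' Takes a library, sample sheet and per-sample observations (either
#' pre-computed counts or cassette FASTQ files to process), applies the
#' negative-control filter, builds the score table, aggregates function
#' scores, classifies LoF variants, sweeps the ST-editing threshold, finds
#' the high-stringency threshold, and (optionally) scores endogenous-target
#' counts and their concordance with the sensor-based scores. Every stage
#' output is written as TSV when `outdir` is given, alongside a manifest of
#' input checksums and per-stage row counts.
#'
#' @param library A `pe_library`.
#' @param samples Validated sample tibble.
#' @param config A [screen_config()].
#' @param observations Per-pegRNA observation tibble covering all samples, or
#'   `NULL` to process `fastq`.
#' @param fastq Tibble with `sample_id`, `fastq1`, `fastq2`; processed when
#'   `observations` is `NULL`.
#' @param et Optional ET count tibble for endogenous scoring.
#' @param sweep_grid Thresholds for [threshold_sweep()].
#' @param outdir Output directory for stage TSVs, or `NULL` to skip writing.
#' @return A list of class `pe_run` with all stage results.
#' @export
run_screen <- function(library, samples, config, observations = NULL,
                       fastq = NULL, et = NULL,
                       sweep_grid = seq(0, 95, by = 5), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  read_stats <- NULL
  if (is.null(observations)) {
    if (is.null(fastq)) abort("Provide either observations or fastq paths.")
    layout <- cassette_layout(library, config$st_anchor_len)
    processed <- stage("process", purrr::map(seq_len(nrow(fastq)), function(i) {
      process_cassette_fastq(fastq$fastq1[i], fastq$fastq2[i], library,
                             config, sample_id = fastq$sample_id[i],
                             layout = layout)
    }))
    observations <- purrr::map_dfr(processed, "observations")
    read_stats <- purrr::map_dfr(processed, "read_stats")
  }
  missing_samples <- setdiff(samples$sample_id,
                             unique(observations$sample_id))
  if (length(missing_samples) > 0) {
    abort(paste0("No observations for sample(s): ",
                 toString(missing_samples)))
  }

  excluded <- stage("negative_control_filter",
                    negative_control_filter(observations, samples, config))
  score_table <- stage("score",
                       build_score_table(observations, samples, library,
                                         config, excluded))
  inform(paste0("Frequency/activity filters: ", sum(score_table$retained),
                " of ", nrow(score_table),
                " (condition, pegRNA) entries retained."))
  min_cond <- if (config$scoring_mode == "multi") 2L else 1L
  fscores <- stage("function_scores",
                   function_scores(score_table, library, config,
                                   min_conditions = min_cond))
  calls <- stage("classify", classify_variants(fscores, config))
  inform(paste0("LoF calls: ", sum(calls$lof_call), " of ", nrow(calls),
                " scored variants at q < ", config$q_cutoff, "."))
  sweep <- stage("sweep",
                 threshold_sweep(score_table, library, config,
                                 grid = sweep_grid,
                                 min_conditions = min_cond))
  mean_st <- mean_variant_st_editing(score_table, library)
  hs <- high_stringency_threshold(calls, mean_st)

  et_res <- NULL
  if (!is.null(et)) {
    et_res <- stage("endogenous",
                    et_function_scores(et, library, samples, config))
    et_res$concordance <- calls |>
      inner_join(et_res$scores, by = "variant_id") |>
      (\(d) list(rho = suppressWarnings(
        stats::cor(d$function_score, d$et_function_score,
                   method = "spearman")), n = nrow(d)))()
  }

  res <- structure(list(
    library = library, samples = samples, config = config,
    observations = observations, read_stats = read_stats,
    excluded_pegrnas = excluded, score_table = score_table,
    function_scores = calls, null = attr(calls, "null"),
    sweep = sweep, mean_st_editing = mean_st,
    high_stringency_threshold = hs, et = et_res
  ), class = "pe_run")

  if (!is.null(outdir)) write_run(res, outdir)
  res
}

#' @export
print.pe_run <- function(x, ...) {
  cat("<pe_run> ", nrow(x$function_scores), " scored variants, ",
      sum(x$function_scores$lof_call), " LoF calls (q < ",
      x$config$q_cutoff, ")\n", sep = "")
  invisible(x)
}

#' @export
glance.pe_run <- function(x, ...) {
  tibble(
    n_pegrnas = nrow(x$library$designs),
    n_variants = nrow(x$library$variants),
    n_excluded_control = length(x$excluded_pegrnas),
    n_retained = sum(x$score_table$retained),
    n_scored = nrow(x$function_scores),
    n_lof = sum(x$function_scores$lof_call),
    auc_at_default = x$sweep$auc[
      which.min(abs(x$sweep$threshold - x$config$st_activity_min_pct))],
    high_stringency_threshold = x$high_stringency_threshold
  )
}

#' Per-consequence score summary
#'
#' Median and IQR of function scores grouped by consequence class, as used in
#' the run report.
#'
#' @param fscores A `pe_function_scores` tibble.
#' @return Summary tibble.
#' @export
consequence_summary <- function(fscores) {
  fscores |>
    group_by(.data$consequence) |>
    summarise(n = n(),
              median_score = stats::median(.data$function_score),
              q1 = stats::quantile(.data$function_score, 0.25),
              q3 = stats::quantile(.data$function_score, 0.75),
              n_lof = if ("lof_call" %in% names(fscores))
                sum(.data$lof_call) else NA_integer_,
              .groups = "drop")
}

write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x, name) {
    if (!is.null(x)) write_screen_table(as_tibble(x),
                                        file.path(outdir, name))
  }
  out(res$observations, "observations.tsv")
  out(res$score_table, "pegrna_scores.tsv")
  out(res$function_scores |> select(-dplyr::any_of("st")),
      "function_scores.tsv")
  out(res$sweep, "threshold_sweep.tsv")
  out(res$mean_st_editing, "mean_st_editing.tsv")
  out(consequence_summary(res$function_scores), "consequence_summary.tsv")
  out(res$read_stats, "read_stats.tsv")
  if (!is.null(res$et)) {
    out(res$et$scores, "et_function_scores.tsv")
    out(res$et$excluded, "et_excluded.tsv")
  }
  manifest <- run_manifest(res, outdir)
  write_screen_table(manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

run_manifest <- function(res, outdir) {
  files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  cfg <- res$config
  cfg_string <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  cfg_file <- file.path(outdir, "config.txt")
  writeLines(cfg_string, cfg_file)
  tibble(
    item = c("config", basename(files)),
    md5 = unname(tools::md5sum(c(cfg_file, files))),
    rows = c(NA_integer_,
             vapply(files, function(f)
               nrow(read_screen_table(f)), integer(1)))
  )
}
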