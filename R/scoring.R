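# pegRNA frequencies, selection scores, filtering, and aggregation into
# variant function scores.

#' Pseudocounted pegRNA frequencies
#'
#' Counts are incremented by 1 and converted to frequencies, so every library
#' pegRNA has a finite, non-zero frequency and log-ratios are always defined:
#' `freq_i = (c_i + 1) / sum_j (c_j + 1)`.
#'
#' @param counts Non-negative integer vector over the full retained library.
#' @return Numeric vector of frequencies summing to 1.
#' @export
pegrna_frequencies <- function(counts) {
  if (length(counts) == 0) abort("Empty library: no counts to convert.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  x <- counts + 1
  x / sum(x)
}

#' pegRNA selection scores
#'
#' The log2 ratio of a pegRNA's pseudocounted frequency in the post-selection
#' sample over the pre-selection sample; finite by construction.
#'
#' @param freq_pre,freq_post Matched frequency vectors.
#' @return Numeric vector of log2 fold changes.
#' @export
pegrna_scores <- function(freq_pre, freq_post) {
  stopifnot(length(freq_pre) == length(freq_post))
  log2(freq_post / freq_pre)
}

#' Collapse replicate samples within a condition
#'
#' Replicate samples of the same condition, timepoint and role have their
#' read counts summed before frequency computation; ST editing percentages
#' are averaged across replicates (ignoring undefined values) before
#' filtering.
#'
#' @param observations Per-pegRNA observation tibble with `sample_id`.
#' @param samples Validated sample tibble.
#' @return Tibble keyed by (`condition`, `timepoint`, `role`, `pegrna_id`)
#'   with summed counts and replicate-averaged editing.
#' @export
collapse_replicates <- function(observations, samples) {
  observations |>
    inner_join(samples |>
                 select("sample_id", "condition", "timepoint", "role"),
               by = "sample_id") |>
    group_by(.data$condition, .data$timepoint, .data$role, .data$pegrna_id) |>
    summarise(
      read_count = sum(.data$read_count),
      st_total = sum(.data$st_total),
      st_correct = sum(.data$st_correct),
      st_editing_pct = if (all(is.na(.data$st_editing_pct))) NA_real_ else
        mean(.data$st_editing_pct, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Build the per-condition pegRNA score table
#'
#' For every condition, pre- and post-selection counts (replicates collapsed)
#' are pseudocounted into frequencies over all pegRNAs surviving the
#' negative-control filter, scored as log2(post/pre), and annotated with the
#' pre-selection ST editing percentage used by the activity filter. Filters
#' are applied afterwards as flags; frequencies are always computed on the
#' full retained library.
#'
#' @param observations Per-pegRNA observation tibble (one row per sample and
#'   pegRNA).
#' @param samples Validated sample tibble.
#' @param library A `pe_library`.
#' @param config A [screen_config()].
#' @param excluded_pegrnas pegRNAs removed by [negative_control_filter()].
#' @return A tibble of class `pe_score_table`: one row per (condition,
#'   pegRNA) with `freq_pre`, `freq_post`, `pegrna_score`,
#'   `st_editing_pre_pct` and filter flags.
#' @export
build_score_table <- function(observations, samples, library, config,
                              excluded_pegrnas = character(0)) {
  coll <- collapse_replicates(observations, samples) |>
    filter(!.data$pegrna_id %in% excluded_pegrnas)
  conds <- samples |>
    filter(.data$role %in% c("pre", "post")) |>
    distinct(.data$condition)
  rows <- purrr::map_dfr(conds$condition, function(cd) {
    pre <- coll |> filter(.data$condition == cd, .data$role == "pre")
    post <- coll |> filter(.data$condition == cd, .data$role == "post")
    if (nrow(pre) == 0 || nrow(post) == 0) return(NULL)
    tab <- pre |>
      select("pegrna_id", pre_count = "read_count",
             st_editing_pre_pct = "st_editing_pct") |>
      inner_join(post |> select("pegrna_id", post_count = "read_count"),
                 by = "pegrna_id")
    tab |>
      mutate(
        condition = cd,
        freq_pre = pegrna_frequencies(.data$pre_count),
        freq_post = pegrna_frequencies(.data$post_count),
        pegrna_score = pegrna_scores(.data$freq_pre, .data$freq_post)
      )
  })
  out <- apply_filters(rows, config)
  attr(out, "excluded_pegrnas") <- excluded_pegrnas
  class(out) <- c("pe_score_table", class(out))
  out
}

#' Flag pegRNAs passing the frequency and activity filters
#'
#' A pegRNA is retained for scoring when its pre-selection frequency is at
#' least `freq_min` and its pre-selection ST editing percentage is at least
#' `st_activity_min_pct`; pegRNAs with undefined editing cannot certify
#' activity and are dropped.
#'
#' @param score_table Tibble with `freq_pre` and `st_editing_pre_pct`.
#' @param config A [screen_config()].
#' @return The table with logical `passed_freq_filter`,
#'   `passed_activity_filter` and `retained` columns.
#' @export
apply_filters <- function(score_table, config) {
  score_table |>
    mutate(
      passed_freq_filter = .data$freq_pre >= config$freq_min,
      passed_activity_filter = !is.na(.data$st_editing_pre_pct) &
        .data$st_editing_pre_pct >= config$st_activity_min_pct,
      retained = .data$passed_freq_filter & .data$passed_activity_filter
    )
}

#' Normalise scores to the neutral median
#'
#' Subtracts (in log2 space) the median score of the neutral entries, so the
#' neutral set is centred at zero.
#'
#' @param scores Numeric vector.
#' @param is_neutral Logical vector marking the neutral entries.
#' @param min_neutral Minimum number of non-missing neutral scores required.
#' @return Normalised numeric vector.
#' @export
normalize_to_neutral <- function(scores, is_neutral, min_neutral = 5) {
  stopifnot(length(scores) == length(is_neutral))
  neut <- scores[is_neutral & !is.na(scores)]
  if (length(neut) < min_neutral) {
    abort(paste0("Only ", length(neut), " neutral scores available; ",
                 min_neutral, " required for normalisation."))
  }
  scores - stats::median(neut)
}

neutral_ids <- function(library) {
  library$variants$variant_id[library$variants$neutral_set]
}

#' Aggregate pegRNA scores into variant function scores
#'
#' Single-condition mode (negative-selection essentiality screens): pegRNA
#' scores are normalised to the neutral median, then averaged over all
#' retained pegRNAs programming the same variant.
#'
#' Multi-condition mode (positive-selection screens across several cell
#' pools): (1) per condition, the mean of retained pegRNA scores per variant;
#' (2) per condition, subtraction of that condition's neutral median function
#' score; (3) unweighted averaging across the conditions in which the variant
#' scored; (4) variants scored in fewer than `min_conditions` conditions are
#' dropped; (5) a final subtraction of the neutral median of the averaged
#' scores.
#'
#' @param score_table A `pe_score_table` (all conditions stacked).
#' @param library A `pe_library`.
#' @param config A [screen_config()]; `scoring_mode` selects the path.
#' @param min_conditions Minimum number of conditions for a final score in
#'   multi-condition mode.
#' @param conditions Optional subset of conditions to aggregate (used for
#'   cell-line-specific scores).
#' @return A tibble of class `pe_function_scores`: per variant, the final
#'   `function_score`, `n_conditions`, `n_pegrnas`, and per-condition scores
#'   in wide columns `score_<condition>`.
#' @export
function_scores <- function(score_table, library, config,
                            min_conditions = 2, conditions = NULL) {
  retained <- score_table |> filter(.data$retained)
  if (!is.null(conditions)) {
    retained <- retained |> filter(.data$condition %in% conditions)
  }
  if (nrow(retained) == 0) abort("No pegRNAs pass the filters.")
  vmap <- library$designs |> select("pegrna_id", "variant_id")
  retained <- retained |> inner_join(vmap, by = "pegrna_id")
  neut <- neutral_ids(library)

  if (config$scoring_mode == "single") {
    one <- retained |>
      group_by(.data$condition) |>
      mutate(norm_score = normalize_to_neutral(
        .data$pegrna_score, .data$variant_id %in% neut,
        config$min_neutral)) |>
      ungroup()
    out <- one |>
      group_by(.data$variant_id) |>
      summarise(function_score = mean(.data$norm_score),
                n_pegrnas = n(),
                n_conditions = dplyr::n_distinct(.data$condition),
                .groups = "drop")
  } else {
    per_cond <- retained |>
      group_by(.data$condition, .data$variant_id) |>
      summarise(cond_score = mean(.data$pegrna_score),
                n_pegrnas = n(), .groups = "drop") |>
      group_by(.data$condition) |>
      mutate(cond_score = normalize_to_neutral(
        .data$cond_score, .data$variant_id %in% neut,
        config$min_neutral)) |>
      ungroup()
    out <- per_cond |>
      group_by(.data$variant_id) |>
      summarise(function_score = mean(.data$cond_score),
                n_pegrnas = sum(.data$n_pegrnas),
                n_conditions = n(), .groups = "drop") |>
      filter(.data$n_conditions >= min_conditions)
    if (nrow(out) == 0) {
      abort(paste0("No variant scored in at least ", min_conditions,
                   " conditions."))
    }
    out <- out |>
      mutate(function_score = normalize_to_neutral(
        .data$function_score, .data$variant_id %in% neut,
        config$min_neutral))
    wide <- per_cond |>
      select("condition", "variant_id", "cond_score") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "cond_score",
                         names_prefix = "score_")
    out <- out |> left_join(wide, by = "variant_id")
  }
  out <- out |>
    left_join(library$variants |>
                select("variant_id", "consequence", "neutral_set",
                       "plof_set"),
              by = "variant_id")
  class(out) <- c("pe_function_scores", class(out))
  out
}

#' Cell-line-specific function scores
#'
#' Condition-specific function scores are computed and normalised as in
#' multi-condition mode, then averaged over the (typically two) conditions
#' using the same cell line, and normalised once more to the neutral median.
#'
#' @param score_table A `pe_score_table`.
#' @param library A `pe_library`.
#' @param config A [screen_config()].
#' @param samples Validated sample tibble mapping conditions to cell lines.
#' @return A tibble: one `pe_function_scores` result per cell line, stacked,
#'   with a `cell_line` column.
#' @export
cellline_scores <- function(score_table, library, config, samples) {
  cells <- samples |>
    filter(.data$role %in% c("pre", "post")) |>
    distinct(.data$cell_line, .data$condition)
  purrr::map_dfr(unique(cells$cell_line), function(cl) {
    conds <- cells$condition[cells$cell_line == cl]
    fs <- function_scores(score_table, library, config,
                          min_conditions = min(2L, length(conds)),
                          conditions = conds)
    mutate(fs, cell_line = cl, .before = 1)
  })
}

#' Mean per-variant surrogate-target editing
#'
#' Averages ST editing percentages over all pegRNAs programming the same
#' variant across conditions; used by the high-stringency threshold search.
#'
#' @param score_table A `pe_score_table` (uses `st_editing_pre_pct`).
#' @param library A `pe_library`.
#' @return Tibble with `variant_id` and `mean_st_editing_pct`.
#' @export
mean_variant_st_editing <- function(score_table, library) {
  score_table |>
    inner_join(library$designs |> select("pegrna_id", "variant_id"),
               by = "pegrna_id") |>
    filter(!is.na(.data$st_editing_pre_pct)) |>
    group_by(.data$variant_id) |>
    summarise(mean_st_editing_pct = mean(.data$st_editing_pre_pct),
              .groups = "drop")
}

#' Correlate pegRNA design features with sensor editing
#'
#' Spearman rank correlation (ties mid-ranked) of each numeric design feature
#' with per-pegRNA ST editing percentages. Constant features yield `NA`.
#'
#' @param editing Tibble with `pegrna_id` and `st_editing_pct` (e.g. one
#'   sample's observations, or replicate-averaged editing).
#' @param designs The `designs` tibble of a `pe_library`.
#' @param features Feature column names; defaults to every feature present.
#' @return Tibble with `feature`, `rho` and `n`.
#' @export
compute_feature_correlations <- function(editing, designs,
                                         features = NULL) {
  features <- features %||% intersect(feature_cols(), names(designs))
  tab <- editing |>
    filter(!is.na(.data$st_editing_pct)) |>
    inner_join(designs |> select(all_of(c("pegrna_id", features))),
               by = "pegrna_id")
  if (nrow(tab) < 3) abort("Need at least 3 pegRNAs with defined editing.")
  purrr::map_dfr(features, function(f) {
    x <- tab[[f]]
    rho <- if (length(unique(x)) < 2) NA_real_ else
      suppressWarnings(stats::cor(x, tab$st_editing_pct,
                                  method = "spearman"))
    tibble(feature = f, rho = rho, n = nrow(tab))
  })
}
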