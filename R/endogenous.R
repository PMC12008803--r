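# Endogenous-target (ET) analysis: background correction, installation
# filters, endogenous function scores, and sensor/genome concordance.

et_exclusion_reasons <- function() {
  c("not_programmed", "high_control_background", "zero_denominator",
    "low_editing_gain")
}

#' Background-correct ET variant frequencies
#'
#' Subtracts the frequency observed in the editor-free negative control
#' (sequencing error background) from each variant's frequency, clamping
#' negative results to zero. Variants whose control frequency exceeds
#' `et_ctrl_freq_max` are excluded outright: such sites are dominated by
#' site-specific sequencing error and cannot be corrected reliably.
#'
#' @param freq Numeric vector of variant frequencies in a sample.
#' @param control_freq Matched control frequencies.
#' @param config A [screen_config()].
#' @return Tibble with `corrected_freq`, `excluded`, `reason`.
#' @export
background_correct <- function(freq, control_freq, config = screen_config()) {
  stopifnot(length(freq) == length(control_freq))
  excluded <- control_freq > config$et_ctrl_freq_max
  tibble(
    corrected_freq = ifelse(excluded, NA_real_,
                            pmax(0, freq - control_freq)),
    excluded = excluded,
    reason = ifelse(excluded, "high_control_background", NA_character_)
  )
}

#' Filter ET variants on editing gain
#'
#' A variant must gain at least `et_min_log2_gain` log2 units of frequency
#' across the editing window (later over earlier pre-selection timepoint) to
#' count as genuinely installed; variants with zero earlier frequency have an
#' undefined ratio and are excluded (no pseudocount is applied at the ET
#' level).
#'
#' @param freq_t2 Frequencies at the later (pre-selection) timepoint.
#' @param freq_t1 Frequencies at the earlier timepoint (or negative control).
#' @param config A [screen_config()].
#' @return Tibble with `log2_gain`, `keep`, `reason`.
#' @export
editing_gain_filter <- function(freq_t2, freq_t1, config = screen_config()) {
  stopifnot(length(freq_t2) == length(freq_t1))
  zero <- freq_t1 <= 0
  gain <- ifelse(zero, NA_real_, log2(freq_t2 / freq_t1))
  keep <- !zero & gain >= config$et_min_log2_gain
  tibble(
    log2_gain = gain,
    keep = keep,
    reason = dplyr::case_when(
      zero ~ "zero_denominator",
      !keep ~ "low_editing_gain",
      TRUE ~ NA_character_
    )
  )
}

#' Endogenous function scores from ET count tables
#'
#' Per condition: variant frequencies are background-corrected against the
#' negative control (with the high-background exclusion), filtered for
#' genuine installation via the editing-gain criterion (later pre-selection
#' timepoint over the earliest available reference), and scored as the log2
#' ratio of post- over pre-selection frequency. Condition scores are
#' normalised to the neutral median, averaged across conditions, and
#' normalised once more. Exclusion reasons are applied in fixed precedence:
#' not programmed, high control background, zero denominator, low editing
#' gain.
#'
#' @param et Tibble from [simulate_et_counts()] or an external counter:
#'   `variant_id`, `sample_id`, `count`, `depth` (and/or `freq`).
#' @param library A `pe_library` (defines programmed variants and the
#'   neutral set).
#' @param samples Validated sample tibble covering the ET samples.
#' @param config A [screen_config()].
#' @return List with `scores` (per-variant tibble: `et_function_score`,
#'   `n_conditions`) and `excluded` (per variant and condition, the first
#'   exclusion reason hit).
#' @export
et_function_scores <- function(et, library, samples, config) {
  if (!"freq" %in% names(et)) {
    et <- et |> mutate(freq = .data$count / .data$depth)
  }
  et <- et |>
    inner_join(samples |>
                 select("sample_id", "condition", "timepoint", "role"),
               by = "sample_id")
  programmed <- unique(library$designs$variant_id)
  not_prog <- setdiff(unique(et$variant_id), programmed)
  et <- et |> filter(.data$variant_id %in% programmed)
  if (nrow(et) == 0) abort("No programmed variants in the ET table.")

  # frequencies averaged across replicate samples where available
  coll <- et |>
    group_by(.data$condition, .data$timepoint, .data$role, .data$variant_id) |>
    summarise(freq = mean(.data$freq), .groups = "drop")

  ctrl <- coll |>
    filter(.data$role == "negative_control") |>
    select("variant_id", control_freq = "freq")
  if (nrow(ctrl) == 0) abort("ET table lacks a negative-control sample.")

  conds <- coll |>
    filter(.data$role %in% c("pre", "post")) |>
    distinct(.data$condition)
  excluded <- list(
    tibble(variant_id = not_prog, condition = NA_character_,
           reason = "not_programmed")
  )
  per_cond <- purrr::map_dfr(conds$condition, function(cd) {
    sub <- coll |> filter(.data$condition == cd)
    pre_t <- sub |> filter(.data$role == "pre")
    post_t <- sub |> filter(.data$role == "post")
    if (nrow(pre_t) == 0 || nrow(post_t) == 0) return(NULL)
    # earliest pre-selection timepoint serves as the editing-gain reference;
    # with a single pre timepoint the negative control takes that role
    pre_times <- sort(unique(pre_t$timepoint))
    pre <- pre_t |> filter(.data$timepoint == max(pre_times))
    early <- if (length(pre_times) > 1) {
      pre_t |> filter(.data$timepoint == min(pre_times))
    } else {
      ctrl |> rename(freq = "control_freq")
    }
    tab <- pre |>
      select("variant_id", freq_pre = "freq") |>
      inner_join(post_t |> select("variant_id", freq_post = "freq"),
                 by = "variant_id") |>
      inner_join(early |> select("variant_id", freq_early = "freq"),
                 by = "variant_id") |>
      inner_join(ctrl, by = "variant_id")

    bc_pre <- background_correct(tab$freq_pre, tab$control_freq, config)
    bc_post <- background_correct(tab$freq_post, tab$control_freq, config)
    tab$corr_pre <- bc_pre$corrected_freq
    tab$corr_post <- bc_post$corrected_freq
    tab$excl_reason <- bc_pre$reason
    gain_ref <- pmax(0, tab$freq_early - ifelse(length(pre_times) > 1,
                                                tab$control_freq, 0))
    zero_pre <- is.na(tab$excl_reason) & tab$corr_pre <= 0
    tab$excl_reason[zero_pre] <- "zero_denominator"
    gf <- editing_gain_filter(tab$corr_pre, gain_ref, config)
    tab$excl_reason <- dplyr::coalesce(tab$excl_reason, gf$reason)
    tab |> mutate(condition = cd)
  })
  per_cond <- per_cond |>
    mutate(et_score = ifelse(is.na(.data$excl_reason) & .data$corr_post > 0 &
                               .data$corr_pre > 0,
                             log2(.data$corr_post / .data$corr_pre),
                             NA_real_),
           excl_reason = ifelse(is.na(.data$excl_reason) &
                                  is.na(.data$et_score),
                                "zero_denominator", .data$excl_reason))

  excluded <- bind_rows(
    bind_rows(excluded),
    per_cond |>
      filter(!is.na(.data$excl_reason)) |>
      select("variant_id", "condition", reason = "excl_reason")
  )

  neut <- neutral_ids(library)
  scored <- per_cond |>
    filter(!is.na(.data$et_score)) |>
    group_by(.data$condition) |>
    mutate(et_score = normalize_to_neutral(
      .data$et_score, .data$variant_id %in% neut, config$min_neutral)) |>
    ungroup() |>
    group_by(.data$variant_id) |>
    summarise(et_function_score = mean(.data$et_score),
              n_conditions = n(), .groups = "drop")
  scored <- scored |>
    mutate(et_function_score = normalize_to_neutral(
      .data$et_function_score, .data$variant_id %in% neut,
      config$min_neutral))
  list(scores = scored, excluded = excluded)
}

#' Per-variant surrogate-target frequencies
#'
#' The fraction of all ST reads in a sample that carry a given variant's
#' edit: the sum of correctly edited ST reads over the variant's pegRNAs,
#' divided by the total ST reads over all pegRNAs in the sample.
#'
#' @param observations Per-pegRNA observation tibble for one or more samples.
#' @param library A `pe_library`.
#' @return Tibble with `sample_id`, `variant_id`, `st_freq`.
#' @export
st_variant_frequencies <- function(observations, library) {
  vmap <- library$designs |> select("pegrna_id", "variant_id")
  observations |>
    inner_join(vmap, by = "pegrna_id") |>
    group_by(.data$sample_id) |>
    mutate(total_st = sum(.data$st_total)) |>
    group_by(.data$sample_id, .data$variant_id) |>
    summarise(st_freq = sum(.data$st_correct) / .data$total_st[1],
              .groups = "drop")
}

#' Sensor/genome concordance
#'
#' Spearman correlation between per-variant ST frequencies (from the
#' cassette sensor) and ET frequencies (from genomic amplicon sequencing),
#' with the paired table returned for plotting.
#'
#' @param st_freqs Tibble from [st_variant_frequencies()] (one sample).
#' @param et_freqs Tibble with `variant_id` and `freq` for the matched ET
#'   sample.
#' @return List with `rho`, `n`, and the paired tibble.
#' @export
st_et_concordance <- function(st_freqs, et_freqs) {
  paired <- st_freqs |>
    inner_join(et_freqs |> select("variant_id", et_freq = "freq"),
               by = "variant_id")
  if (nrow(paired) < 3) abort("Fewer than 3 paired variants.")
  rho <- suppressWarnings(stats::cor(paired$st_freq, paired$et_freq,
                                     method = "spearman"))
  list(rho = rho, n = nrow(paired), pairs = paired)
}
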