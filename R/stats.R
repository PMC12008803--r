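# LoF classification against an empirical normal null, BH correction, and
# ST-editing threshold diagnostics (AUC sweep, high-stringency threshold).

#' Fit the empirical neutral null
#'
#' Models the distribution of neutral (e.g. synonymous) function scores as a
#' normal with moment estimates: `mu` the sample mean and `sigma` the sample
#' standard deviation (n-1 denominator).
#'
#' @param neutral_scores Numeric vector of neutral-variant function scores.
#' @param min_neutral Minimum number of scores required.
#' @param tail `"lower"` for depletion screens (LoF drops out) or `"upper"`
#'   for enrichment screens.
#' @return An object of class `pe_null` with fields `mu`, `sigma`,
#'   `n_neutral`, `tail`.
#' @export
fit_null <- function(neutral_scores, min_neutral = 5,
                     tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  x <- neutral_scores[!is.na(neutral_scores)]
  if (length(x) < min_neutral) {
    abort(paste0("Need at least ", min_neutral, " neutral scores; got ",
                 length(x), "."))
  }
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma == 0) {
    abort("Neutral scores are constant; the null has zero variance.")
  }
  structure(list(mu = mean(x), sigma = sigma, n_neutral = length(x),
                 tail = tail),
            class = "pe_null")
}

#' @export
print.pe_null <- function(x, ...) {
  cat(sprintf("<pe_null> N(mu = %.4g, sigma = %.4g) from %d neutral scores, %s tail\n",
              x$mu, x$sigma, x$n_neutral, x$tail))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pe_null <- function(x, ...) {
  tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @export
glance.pe_null <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, n_neutral = x$n_neutral, tail = x$tail)
}

#' Tail probabilities under the neutral null
#'
#' One-sided p-values in the selection direction: for a depletion screen the
#' lower tail (how far below the neutral distribution a score falls), for an
#' enrichment screen the upper tail. `one_sided = FALSE` doubles the smaller
#' tail.
#'
#' @param scores Numeric vector of function scores.
#' @param null A [fit_null()] object.
#' @param one_sided Logical.
#' @return Numeric vector of p-values.
#' @export
null_p_values <- function(scores, null, one_sided = TRUE) {
  stopifnot(inherits(null, "pe_null"))
  lower <- stats::pnorm(scores, null$mu, null$sigma)
  p <- if (null$tail == "lower") lower else 1 - lower
  if (!one_sided) p <- pmin(1, 2 * pmin(lower, 1 - lower))
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment over the family of all variants receiving
#' a final function score in the screen.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values (monotone, ties preserved).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Call loss-of-function variants
#'
#' A variant is called LoF when its q-value is strictly below the cutoff.
#'
#' @param q Numeric vector of q-values.
#' @param q_cutoff Cutoff (e.g. 0.05 or 0.01 depending on the screen).
#' @return Logical vector.
#' @export
call_lof <- function(q, q_cutoff = 0.05) {
  if (length(q) == 0) return(logical(0))
  q < q_cutoff
}

#' Classify variants in a function-score table
#'
#' Fits the neutral null from the screen's neutral set, computes one-sided
#' p-values in the selection direction, BH-adjusts them over all scored
#' variants, and calls LoF at the configured q cutoff.
#'
#' @param fscores A `pe_function_scores` tibble.
#' @param config A [screen_config()].
#' @return The table with `p_value`, `q_value` and `lof_call` columns; the
#'   fitted `pe_null` is attached as attribute `null`.
#' @export
classify_variants <- function(fscores, config) {
  tail <- if (config$selection_direction == "depletion") "lower" else "upper"
  null <- fit_null(fscores$function_score[fscores$neutral_set],
                   min_neutral = config$min_neutral, tail = tail)
  out <- fscores |>
    mutate(p_value = null_p_values(.data$function_score, null,
                                   one_sided = config$one_sided),
           q_value = bh_adjust(.data$p_value),
           lof_call = call_lof(.data$q_value, config$q_cutoff))
  attr(out, "null") <- null
  out
}

#' Rank-based AUC for separating pLoF from pNeut variants
#'
#' The probability that a randomly chosen putative-LoF variant outscores a
#' randomly chosen putative-neutral variant in the selection direction, with
#' ties counting one half (equivalent to the Mann-Whitney statistic).
#'
#' @param is_plof Logical vector marking the pLoF class.
#' @param scores Numeric function scores.
#' @param direction `"depletion"` (more negative = more LoF-like) or
#'   `"enrichment"` (more positive = more LoF-like).
#' @return AUC in `[0, 1]`, or `NA` if either class is empty.
#' @export
auc_lof <- function(is_plof, scores, direction = c("depletion", "enrichment")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(is_plof)
  is_plof <- is_plof[keep]
  scores <- scores[keep]
  n1 <- sum(is_plof)
  n0 <- sum(!is_plof)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  s <- if (direction == "depletion") -scores else scores
  r <- rank(s)
  (sum(r[is_plof]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sweep the ST-editing activity threshold
#'
#' At each threshold of the grid, the activity filter is re-applied (pegRNAs
#' with pre-selection ST editing below the threshold are dropped), function
#' scores are recomputed on the re-filtered set, and the pLoF/pNeut AUC is
#' evaluated. Thresholds retaining no scorable variants yield `NA` AUC.
#'
#' @param score_table A `pe_score_table` (all conditions).
#' @param library A `pe_library`.
#' @param config A [screen_config()].
#' @param grid Numeric vector of editing thresholds (percent); default 0-95
#'   in steps of 5.
#' @param min_conditions Passed to [function_scores()] in multi mode.
#' @return A tibble of class `pe_sweep`: `threshold`, `auc`,
#'   `n_pegrnas_retained`, `n_variants_scored`.
#' @export
threshold_sweep <- function(score_table, library, config,
                            grid = seq(0, 95, by = 5), min_conditions = 2) {
  grid <- sort(unique(grid))
  rows <- purrr::map_dfr(grid, function(t) {
    cfg <- config
    cfg$st_activity_min_pct <- t
    tab <- apply_filters(score_table, cfg)
    n_ret <- sum(tab$retained)
    fs <- tryCatch(
      function_scores(tab, library, cfg, min_conditions = min_conditions),
      error = function(e) NULL
    )
    if (is.null(fs)) {
      return(tibble(threshold = t, auc = NA_real_,
                    n_pegrnas_retained = n_ret, n_variants_scored = 0L))
    }
    bench <- fs |> filter(.data$plof_set | .data$neutral_set)
    tibble(
      threshold = t,
      auc = auc_lof(bench$plof_set, bench$function_score,
                    config$selection_direction),
      n_pegrnas_retained = n_ret,
      n_variants_scored = nrow(fs)
    )
  })
  class(rows) <- c("pe_sweep", class(rows))
  rows
}

#' @export
glance.pe_sweep <- function(x, ...) {
  tibble(best_auc = max(x$auc, na.rm = TRUE),
         threshold_at_best = x$threshold[which.max(x$auc)],
         n_thresholds = nrow(x))
}

#' High-stringency mean-ST-editing threshold
#'
#' The smallest grid value `t` such that, among variants whose mean ST
#' editing is at least `t`, the range of pLoF function scores does not
#' overlap the range of pNeut function scores. Returns `NA` when no
#' threshold achieves separation (including when either class empties out).
#'
#' @param fscores A `pe_function_scores` tibble.
#' @param mean_st Tibble from [mean_variant_st_editing()].
#' @param grid Candidate thresholds (percent); default 0-100 in steps of 1.
#' @return A single threshold (percent) or `NA`.
#' @export
high_stringency_threshold <- function(fscores, mean_st,
                                      grid = seq(0, 100, by = 1)) {
  tab <- fscores |>
    inner_join(mean_st, by = "variant_id") |>
    filter(.data$plof_set | .data$neutral_set)
  for (t in sort(grid)) {
    sub <- tab |> filter(.data$mean_st_editing_pct >= t)
    lof <- sub$function_score[sub$plof_set]
    neut <- sub$function_score[sub$neutral_set]
    if (length(lof) == 0 || length(neut) == 0) next
    disjoint <- max(lof) < min(neut) || max(neut) < min(lof)
    if (disjoint) return(t)
  }
  NA_real_
}
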