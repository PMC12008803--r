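# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_boxplot geom_line geom_point
#'   geom_violin geom_hline labs theme_bw autoplot sec_axis scale_y_continuous
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Function scores by consequence class
#'
#' @param fscores A `pe_function_scores` tibble.
#' @return A ggplot: boxplots of function scores per consequence.
#' @export
plot_score_by_consequence <- function(fscores) {
  ggplot(fscores, aes(x = stats::reorder(.data$consequence,
                                         .data$function_score,
                                         stats::median),
                      y = .data$function_score)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = NULL, y = "function score (log2)") +
    theme_bw()
}

#' AUC and pegRNA retention across ST-editing thresholds
#'
#' @param object A `pe_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot with the pLoF/pNeut AUC as a line and the number of
#'   retained pegRNAs on a secondary axis.
#' @export
autoplot.pe_sweep <- function(object, ...) {
  scale <- max(object$n_pegrnas_retained)
  ggplot(object, aes(x = .data$threshold)) +
    geom_line(aes(y = .data$auc), colour = "#2166ac") +
    geom_point(aes(y = .data$auc), colour = "#2166ac") +
    geom_line(aes(y = .data$n_pegrnas_retained / scale), colour = "grey40",
              linetype = "dotted") +
    scale_y_continuous(
      name = "AUC (pLoF vs pNeut)",
      sec.axis = sec_axis(~ . * scale, name = "pegRNAs retained")
    ) +
    labs(x = "ST editing threshold (%)") +
    theme_bw()
}

#' Distribution of ST editing across samples
#'
#' @param observations Per-pegRNA observation tibble.
#' @param samples Validated sample tibble (for ordering by timepoint).
#' @return A ggplot: violins of ST editing percentage per sample.
#' @export
plot_editing_distribution <- function(observations, samples) {
  ord <- samples |> arrange(.data$timepoint, .data$sample_id)
  dat <- observations |>
    filter(!is.na(.data$st_editing_pct)) |>
    mutate(sample_id = factor(.data$sample_id, levels = ord$sample_id))
  ggplot(dat, aes(x = .data$sample_id, y = .data$st_editing_pct)) +
    geom_violin(fill = "grey85") +
    labs(x = NULL, y = "correct ST editing (%)") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Sensor vs genomic variant frequencies
#'
#' @param concordance Result of [st_et_concordance()].
#' @return A ggplot scatter of ST against ET variant frequencies.
#' @export
plot_st_et_concordance <- function(concordance) {
  ggplot(concordance$pairs, aes(x = .data$st_freq, y = .data$et_freq)) +
    geom_point(alpha = 0.6) +
    labs(x = "ST variant frequency", y = "ET variant frequency",
         subtitle = sprintf("Spearman rho = %.2f (n = %d)",
                            concordance$rho, concordance$n)) +
    theme_bw()
}
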