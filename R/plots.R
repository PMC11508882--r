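#' Plot a ROC staircase
#'
#' @param object A `pgs_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pgs_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Score distributions by group
#'
#' Density of a per-sample score split by a grouping column — the standard
#' view of case/control or macro-area distribution shifts.
#'
#' @param data Tibble holding the score and the grouping column.
#' @param score_col Name of the score column.
#' @param by Name of the grouping column (default `"status"`).
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(data, score_col, by = "status") {
  ggplot2::ggplot(data, ggplot2::aes(.data[[score_col]],
                                     fill = .data[[by]],
                                     colour = .data[[by]])) +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::labs(x = score_col, y = "Density") +
    ggplot2::theme_minimal()
}

#' Forest plot of percentile-threshold odds ratios
#'
#' @param or_tbl A `percentile_or` tibble (possibly over several scores,
#'   with a `pgs_id` column).
#' @return A ggplot object; the OR axis is logarithmic and the null line
#'   at OR = 1 is drawn.
#' @export
plot_percentile_or <- function(or_tbl) {
  or_tbl <- dplyr::filter(or_tbl, is.finite(.data$odds_ratio),
                          .data$odds_ratio > 0)
  or_tbl$threshold <- factor(sprintf("> %gth", 100 * or_tbl$q))
  p <- ggplot2::ggplot(
    or_tbl, ggplot2::aes(.data$threshold, .data$odds_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Score percentile threshold",
                  y = "Odds ratio (95% CI)") +
    ggplot2::theme_minimal()
  if ("pgs_id" %in% names(or_tbl)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$pgs_id))
  }
  p
}

#' AUC comparison plot for a model suite
#'
#' Point-range AUCs with DeLong CIs for the covariates-only, score-only
#' and combined models of each score.
#'
#' @param object A `pgs_model_suite`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pgs_model_suite <- function(object, ...) {
  cmp <- object$comparison
  cmp$pgs_id[is.na(cmp$pgs_id)] <- "(covariates)"
  ggplot2::ggplot(cmp, ggplot2::aes(.data$pgs_id, .data$auc,
                                    colour = .data$model)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = NULL, y = "Test-set AUC (95% CI)") +
    ggplot2::theme_minimal()
}
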