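#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adherence_roc
#' @export
autoplot.adherence_roc <- function(object, ...) {
  auc <- roc_auc(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s at FST %s h", attr(object, "comparison"),
                      attr(object, "fst_h")),
      subtitle = sprintf("trapezoid AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Plot scenario concentration distributions across sampling times
#'
#' Median and interquartile band of the simulated dose-normalized
#' concentrations for each adherence scenario as a function of the first
#' sampling time.
#'
#' @param object A [simulate_scenarios()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_grid
#' @export
autoplot.scenario_grid <- function(object, ...) {
  summ <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$scenario, .data$fst_h) |>
    dplyr::summarise(
      med = stats::median(.data$conc_norm),
      lo = stats::quantile(.data$conc_norm, 0.25),
      hi = stats::quantile(.data$conc_norm, 0.75),
      .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$fst_h, y = .data$med,
                                     colour = .data$scenario,
                                     fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "First sampling time (h after last dose)",
                  y = "Dose-normalized concentration (nmol/mg/L)",
                  colour = "Scenario", fill = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot the support points of a fitted population model
#'
#' Weight bar charts of the fitted discrete distribution, one panel per
#' random effect.
#'
#' @param object An [np_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_fit
#' @export
autoplot.np_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$support,
                              cols = c("ka", "ke", "v"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$value, yend = 0),
                          linewidth = 1.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "Support point value", y = "Probability weight",
                  title = sprintf("Nonparametric population model (%s)",
                                  object$analyte)) +
    ggplot2::theme_minimal()
}

#' Plot ROC performance against sampling time
#'
#' Sensitivity/specificity bars at the optimal-difference cutoff with the
#' AUC trend overlaid, per first sampling time.
#'
#' @param summary_tbl A [roc_summary()] result.
#' @return A ggplot object.
#' @export
plot_roc_by_fst <- function(summary_tbl) {
  long <- tidyr::pivot_longer(summary_tbl,
                              cols = c("sensitivity", "specificity"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fst_h)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$value, fill = .data$measure),
                      position = "dodge", width = 0.8) +
    ggplot2::geom_line(data = summary_tbl,
                       ggplot2::aes(y = .data$auc), colour = "grey30",
                       linewidth = 0.9) +
    ggplot2::facet_wrap(~comparison, ncol = 1) +
    ggplot2::labs(x = "First sampling time (h)", y = NULL,
                  fill = NULL,
                  title = "Adherence discrimination by sampling time",
                  subtitle = "Bars: sensitivity/specificity at the optimal-difference cutoff; line: AUC") +
    ggplot2::theme_minimal()
}
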