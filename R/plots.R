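#' Scatter plot of MA versus MLR effect size estimates
#'
#' One point per phenomenon (meta-analytic pooled estimate on x, MLR
#' estimate on y) with the least-squares line and a dashed identity
#' reference; points below the identity line are phenomena where the
#' meta-analysis estimates a larger effect than the replication.
#'
#' @param report An `mlr_comparison` from [run_full_comparison()].
#' @return A ggplot object.
#' @export
plot_estimate_scatter <- function(report) {
  stopifnot(inherits(report, "mlr_comparison"))
  per <- report$per_phenomenon
  p <- ggplot2::ggplot(per, ggplot2::aes(x = .data$naive_mu,
                                         y = .data$mlr_estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Meta-analytic estimate (SMD)",
                  y = "MLR estimate (SMD)") +
    ggplot2::theme_minimal()
  if (!is.null(report$correlation)) {
    corr <- report$correlation
    p <- p +
      ggplot2::geom_abline(slope = corr$slope, intercept = corr$intercept,
                           colour = "steelblue") +
      ggplot2::labs(subtitle = sprintf(
        "r = %.2f [%.2f, %.2f]; MLR = %.2f + %.2f × MA",
        corr$r, corr$ci_low, corr$ci_high, corr$intercept, corr$slope))
  }
  p
}

#' Forest-style sensitivity plot
#'
#' Per phenomenon: the naive pooled estimate (triangle), the worst-case
#' publication-bias estimate (vertical tick), and the MLR estimate
#' (circle), with the calibrated percentage of population effects at or
#' below the MLR estimate printed on the right (CI shown when estimable).
#' Phenomena whose worst-case estimate exceeds the MLR estimate are ones
#' where no amount of this form of publication bias can explain the gap.
#'
#' @param report An `mlr_comparison` from [run_full_comparison()].
#' @return A ggplot object.
#' @export
plot_sensitivity_forest <- function(report) {
  stopifnot(inherits(report, "mlr_comparison"))
  per <- report$per_phenomenon
  per$phenomenon_id <- factor(per$phenomenon_id,
                              levels = rev(per$phenomenon_id))
  per$phat_label <- ifelse(
    per$phat_ci_estimable,
    sprintf("%.0f%% [%.0f%%, %.0f%%]", 100 * per$phat,
            100 * per$phat_ci_low, 100 * per$phat_ci_high),
    sprintf("%.0f%%", 100 * per$phat))

  long <- tidyr::pivot_longer(
    per[, c("phenomenon_id", "naive_mu", "worst_case_mu", "mlr_estimate")],
    cols = c("naive_mu", "worst_case_mu", "mlr_estimate"),
    names_to = "quantity", values_to = "estimate")
  long$quantity <- factor(long$quantity,
                          levels = c("naive_mu", "worst_case_mu",
                                     "mlr_estimate"),
                          labels = c("Naive", "Worst-case", "MLR"))

  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate,
                                     y = .data$phenomenon_id,
                                     shape = .data$quantity)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 2.5, na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(Naive = 17, `Worst-case` = 124,
                                           MLR = 16)) +
    ggplot2::geom_text(
      data = per,
      ggplot2::aes(x = max(long$estimate, na.rm = TRUE) + 0.15,
                   y = .data$phenomenon_id, label = .data$phat_label),
      inherit.aes = FALSE, hjust = 0, size = 3) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::labs(x = "Effect size (SMD)", y = NULL, shape = NULL,
                  caption = paste("Right margin: estimated % of population",
                                  "effects ≤ MLR estimate")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(plot.margin = ggplot2::margin(5.5, 90, 5.5, 5.5))
}

#' @rdname plot_estimate_scatter
#' @param object An `mlr_comparison` object.
#' @param ... Unused.
#' @export
autoplot.mlr_comparison <- function(object, ...) {
  plot_estimate_scatter(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
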