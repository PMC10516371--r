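#' Plot a factorial benchmarking summary
#'
#' One panel per metric, methods on the x axis, points per baseline/batch
#' cell, with the nominal level marked for the error metrics -- the
#' small-multiples view used to compare type I error, FDR and sensitivity
#' across methods and scenarios.
#'
#' @param object A `zi_grid_eval` tibble from [run_parametric_grid()].
#' @param metrics Metrics to show.
#' @param alpha Nominal level drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zi_grid_eval <- function(object,
                                  metrics = c("type1", "fdr", "sensitivity"),
                                  alpha = 0.05, ...) {
  long <- object %>%
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value") %>%
    mutate(baseline = sprintf("mu=%g, th=%g, pi=%g", .data$mu, .data$theta, .data$pi))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     colour = .data$batch,
                                     shape = .data$baseline)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(metric ~ disease, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "batch", shape = "baseline") +
    ggplot2::theme_bw()
}

#' Plot sensitivity-vs-cutoff curves
#'
#' @param curves A tibble from [sensitivity_curve()], optionally with a
#'   `method` column to draw one curve per method.
#' @return A ggplot.
#' @export
plot_sensitivity_curve <- function(curves) {
  aes <- if ("method" %in% names(curves)) {
    ggplot2::aes(x = .data$cutoff, y = .data$sensitivity, colour = .data$method)
  } else {
    ggplot2::aes(x = .data$cutoff, y = .data$sensitivity)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "p-value cutoff", y = "sensitivity") +
    ggplot2::theme_bw()
}

#' Plot goodness-of-fit p-value histograms
#'
#' Histograms of Lilliefors p-values per family-by-transform pair; a
#' well-fitting family shows a flat histogram.
#'
#' @param gof A tibble from [gof_survey()].
#' @return A ggplot.
#' @export
plot_gof <- function(gof) {
  ggplot2::ggplot(dplyr::filter(gof, !is.na(.data$p_value)),
                  ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "steelblue", colour = "white") +
    ggplot2::facet_grid(family ~ transform) +
    ggplot2::labs(x = "Lilliefors p-value", y = "genes") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
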