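#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synchrony series
#'
#' Time course of the rolling correlation and instantaneous phase synchrony,
#' one panel row per measure, faceted by trial.
#'
#' @param object A `rip_synchrony` tibble from [compute_rip_synchrony()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rip_synchrony <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("correlation", "phase_synchrony"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey20") +
    ggplot2::facet_grid(measure ~ trial, scales = "free_y") +
    ggplot2::labs(x = "Time in trial (s)", y = NULL,
                  title = "Chest-abdomen rolling correlation and phase synchrony") +
    ggplot2::theme_minimal()
}

#' Decile profile of a metric across trials
#'
#' Decile means (with across-subject SD ribbon when several subjects are
#' present) of one metric, one panel per trial — the standard way of
#' looking at within-trial drift of synchrony or EMG features.
#'
#' @param decile_table Long decile tibble.
#' @param metric Metric name to plot.
#' @return A ggplot object.
#' @export
plot_decile_profile <- function(decile_table, metric) {
  d <- dplyr::filter(decile_table, .data$metric == !!metric) |>
    dplyr::group_by(.data$trial, .data$division) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$division, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, fill = "steelblue", na.rm = TRUE) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~trial) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Trial division (decile)", y = metric) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a trial/division mixed model
#'
#' @param object A `tdm_fit` from [fit_trial_division_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tdm_fit <- function(object, ...) {
  d <- dplyr::filter(object$terms, .data$term != "(Intercept)") |>
    dplyr::mutate(sig = .data$p < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(.data$beta, stats::reorder(.data$term, .data$beta),
                                  colour = .data$sig)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = "p < 0.05") +
    ggplot2::labs(x = "Fixed-effect estimate (transformed scale)", y = NULL,
                  title = paste("Mixed model:", object$dependent)) +
    ggplot2::theme_minimal()
}
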