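# convenience figures

#' Step-size distribution with the pause/motion threshold
#'
#' Histogram of pooled step sizes at the data's sampling period, split at
#' the fitted percentile threshold: the low-speed (pause) mass versus the
#' motion mass. Log-scaled x axis, because the two modes typically sit
#' orders of magnitude apart.
#'
#' @param data A `tandem_pairs` tibble at the period of interest.
#' @param q Threshold percentile (default 10).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_step_sizes <- function(data, q = 10, bins = 60) {
  sizes <- step_sizes(data)
  thr <- pause_threshold(data, q = q)
  sizes$state <- ifelse(sizes$step_mm <= thr$threshold_mm[1], "pause", "motion")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$step_mm, fill = .data$state)) +
    ggplot2::geom_histogram(bins = bins, colour = NA) +
    ggplot2::geom_vline(xintercept = thr$threshold_mm[1], linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(pause = "#762a83", motion = "#1b7837")) +
    ggplot2::labs(
      x = "step size (mm)", y = "steps",
      title = sprintf("Step sizes at %.4f s (threshold %.3g mm, q = %g%%)",
                      meta(sizes, "period_s"), thr$threshold_mm[1], q)
    ) +
    ggplot2::theme_minimal()
}

#' Local transfer entropy values over time
#'
#' @param object A `local_te` tibble.
#' @param ... Unused.
#' @return A ggplot object (one facet per trial; the dashed line is the
#'   pooled TE, i.e. the mean local value).
#' @method autoplot local_te
#' @export
autoplot.local_te <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_index, y = .data$local_bits)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = attr(object, "te_bits", exact = TRUE),
                        linetype = 2) +
    ggplot2::geom_line(linewidth = 0.2, alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trial_id)) +
    ggplot2::labs(
      x = "time index", y = "local transfer entropy (bits)",
      title = paste0("Local information flow ",
                     attr(object, "direction", exact = TRUE))
    ) +
    ggplot2::theme_minimal()
}
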