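# parameter-landscape sweep over (sampling period x history length)

#' Sweep net transfer entropy over sampling periods and history lengths
#'
#' For each sampling period the trajectories are re-subsampled, the pause
#' threshold refit (for pause-bearing patterns), the pattern re-encoded,
#' and for each history length the pooled net transfer entropy computed.
#' The default axes (k in 1..20 crossed with the 45 multiples of the
#' native sampling interval) give 900 configurations. Cells are raw
#' (uncorrected) net TE; the surrogate correction belongs at the selected
#' configuration, not across the grid. A cell is invalid when any trial
#' yields fewer than k+1 symbols at that period; invalid cells carry `NA`
#' and are excluded from selection.
#'
#' @param data A `tandem_pairs` tibble at its native sampling period.
#' @param pattern Encoding pattern name.
#' @param k_values Integer history lengths (default `1:20`).
#' @param periods_s Sampling periods in seconds (default
#'   `default_periods(frame_rate)` of the data).
#' @param q Pause-threshold percentile for pause-bearing patterns.
#' @return A tibble of class `te_landscape`: columns `k`, `period_s`,
#'   `te_lf_bits`, `te_fl_bits`, `net_bits`, `valid`.
#' @export
sweep_net_te <- function(data, pattern = c("pausing", "rotation", "compound"),
                         k_values = 1:20, periods_s = NULL, q = 10) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(data, "tandem_pairs"))
  if (length(k_values) == 0) stop_tf("empty history-length axis")
  periods_s <- periods_s %||% default_periods(meta(data, "frame_rate"))
  if (length(periods_s) == 0) stop_tf("empty period axis")

  per_period <- purrr::map(periods_s, function(p) {
    sub <- subsample_trajectories(data, p)
    symbols <- encode_pattern(sub, pattern, q = q)
    min_len <- min(dplyr::count(symbols, .data$trial_id, .data$role)$n)
    rows <- purrr::map(k_values, function(k) {
      if (min_len < k + 1) {
        return(tibble::tibble(
          k = as.integer(k), period_s = meta(symbols, "period_s"),
          te_lf_bits = NA_real_, te_fl_bits = NA_real_,
          net_bits = NA_real_, valid = FALSE
        ))
      }
      net <- net_transfer_entropy(symbols, k_lf = k, k_fl = k)
      tibble::tibble(
        k = as.integer(k), period_s = net$period_s,
        te_lf_bits = net$te_lf_bits, te_fl_bits = net$te_fl_bits,
        net_bits = net$net_bits, valid = TRUE
      )
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(per_period)
  structure(
    out,
    pattern = pattern,
    species = meta(data, "species"),
    q = q,
    class = c("te_landscape", class(tibble::tibble()))
  )
}

#' Select the configuration maximizing net information transfer
#'
#' Picks the valid cell with maximal absolute net transfer entropy (the
#' follower can be the predominant source, so magnitude, not signed value,
#' is maximized); ties break toward smaller k, then shorter period.
#'
#' @param grid A `te_landscape` tibble.
#' @return One-row tibble: `k`, `period_s`, `net_bits`, `te_lf_bits`,
#'   `te_fl_bits`.
#' @export
select_max_config <- function(grid) {
  stopifnot(inherits(grid, "te_landscape"))
  valid <- dplyr::filter(grid, .data$valid)
  if (nrow(valid) == 0) stop_tf("no valid cell in the landscape")
  valid <- dplyr::arrange(valid, dplyr::desc(abs(.data$net_bits)),
                          .data$k, .data$period_s)
  valid[1, c("k", "period_s", "net_bits", "te_lf_bits", "te_fl_bits")]
}

#' Robustness of flow direction to the pause-threshold percentile
#'
#' Re-encodes a pause-bearing pattern at each percentile q (default 5..15)
#' and recomputes pooled net transfer entropy at a fixed history length and
#' sampling period. The recovered direction is robust when the sign of net
#' TE is constant across the whole interval.
#'
#' @inheritParams sweep_net_te
#' @param q_values Percentiles to scan (default `5:15`).
#' @param k History length.
#' @param period_s Sampling period, seconds.
#' @return A tibble of class `te_perturbation` with columns `q`,
#'   `net_bits`, `te_lf_bits`, `te_fl_bits`; attribute
#'   `direction_stable` is `TRUE` iff the sign of `net_bits` never
#'   changes.
#' @export
threshold_perturbation <- function(data, pattern = c("pausing", "compound"),
                                   q_values = 5:15, k, period_s) {
  pattern <- match.arg(pattern)
  if (identical(pattern, "rotation")) {
    stop_tf("the rotation pattern has no pause threshold to perturb")
  }
  sub <- subsample_trajectories(data, period_s)
  rows <- purrr::map(q_values, function(q) {
    symbols <- encode_pattern(sub, pattern, q = q)
    net <- net_transfer_entropy(symbols, k_lf = k, k_fl = k)
    tibble::tibble(q = q, net_bits = net$net_bits,
                   te_lf_bits = net$te_lf_bits, te_fl_bits = net$te_fl_bits)
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    pattern = pattern, k = as.integer(k), period_s = period_s,
    direction_stable = length(unique(sign(out$net_bits))) == 1L,
    class = c("te_perturbation", class(tibble::tibble()))
  )
}

#' Is the recovered flow direction stable under threshold perturbation?
#'
#' @param x A `te_perturbation` tibble.
#' @return Logical flag.
#' @export
direction_stable <- function(x) {
  stopifnot(inherits(x, "te_perturbation"))
  isTRUE(attr(x, "direction_stable", exact = TRUE))
}

#' Heat-map of a net-transfer-entropy landscape
#'
#' @param object A `te_landscape` tibble.
#' @param ... Unused.
#' @return A ggplot object (period on x, history length on y, net TE as
#'   fill; the selected maximum is marked).
#' @method autoplot te_landscape
#' @export
autoplot.te_landscape <- function(object, ...) {
  best <- select_max_config(object)
  ggplot2::ggplot(
    dplyr::filter(object, .data$valid),
    ggplot2::aes(x = .data$period_s, y = .data$k, fill = .data$net_bits)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#1b7837", mid = "white", high = "#762a83", midpoint = 0,
      name = "net TE (bits)"
    ) +
    ggplot2::geom_point(
      data = best, ggplot2::aes(x = .data$period_s, y = .data$k),
      inherit.aes = FALSE, shape = 5, size = 3, colour = "red"
    ) +
    ggplot2::labs(
      x = "sampling period (s)", y = "history length k",
      title = paste0("Net information transfer (", meta(object, "pattern"), ")"),
      subtitle = "purple: leader to follower; green: follower to leader"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
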