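# distance- and speed-resolved views of local information flow

#' Inter-centroid distance between leader and follower
#'
#' Euclidean distance at every aligned time step, in millimetres and in
#' species body lengths (the cross-species distance unit). Because
#' trajectories track body centroids, the distance is strictly positive
#' even when the runners touch; a zero distance violates that contract and
#' raises an error.
#'
#' @param data A `tandem_pairs` tibble (already subsampled to the analysis
#'   period) whose `body_length_mm` attribute is set.
#' @return Tibble with columns `trial_id`, `t_index`, `dist_mm`,
#'   `dist_bl`.
#' @export
pair_distances <- function(data) {
  stopifnot(inherits(data, "tandem_pairs"))
  bl <- meta(data, "body_length_mm")
  if (is.null(bl) || is.na(bl) || bl <= 0) {
    stop_tf("body_length_mm attribute must be a positive number")
  }
  wide <- tidyr::pivot_wider(
    data[, c("trial_id", "role", "t_index", "x", "y")],
    names_from = "role", values_from = c("x", "y")
  )
  if (anyNA(wide$x_leader) || anyNA(wide$x_follower)) {
    stop_tf("misaligned leader/follower positions")
  }
  out <- dplyr::transmute(
    wide,
    trial_id = .data$trial_id, t_index = .data$t_index,
    dist_mm = sqrt((.data$x_leader - .data$x_follower)^2 +
                   (.data$y_leader - .data$y_follower)^2),
    dist_bl = .data$dist_mm / bl
  )
  if (any(out$dist_mm == 0)) {
    stop_tf("zero inter-centroid distance (centroid tracks must never coincide)")
  }
  restore_meta(tibble::as_tibble(out), data)
}

# equal-width binning + LOESS smoothing of a signal against distance;
# falls back to the raw bin means when too few bins support a local fit
bin_and_smooth <- function(dist_bl, value, span, bin_width_bl) {
  centers <- (floor(dist_bl / bin_width_bl) + 0.5) * bin_width_bl
  binned <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(center = centers, value = value),
                    .data$center),
    mean_value = mean(.data$value), n = dplyr::n(), .groups = "drop"
  )
  binned <- dplyr::arrange(binned, .data$center)
  if (nrow(binned) >= 10) {
    fit <- suppressWarnings(stats::loess(
      mean_value ~ center, data = binned, span = span, degree = 2,
      weights = binned$n
    ))
    binned$smoothed_value <- unname(stats::predict(fit, binned$center))
  } else {
    binned$smoothed_value <- binned$mean_value
  }
  binned
}

#' Average local transfer entropy as a function of pair distance
#'
#' Joins a local transfer-entropy series with the inter-centroid distance
#' series (on trial and time index), bins by distance in body lengths, and
#' smooths the conditional means with LOESS. The count-weighted mean over
#' bins equals the overall mean local TE, i.e. the pooled transfer
#' entropy (conservation holds before smoothing).
#'
#' @param local A `local_te` tibble from [local_transfer_entropy()].
#' @param dist A distance tibble from [pair_distances()] at the same
#'   sampling period.
#' @param span LOESS span (default 0.3).
#' @param bin_width_bl Bin width in body lengths (default 0.1).
#' @return A tibble of class `te_profile`: `dist_bl` (bin center),
#'   `mean_value` (bits), `n`, `smoothed_value`.
#' @export
local_te_by_distance <- function(local, dist, span = 0.3,
                                 bin_width_bl = 0.1) {
  stopifnot(inherits(local, "local_te"))
  joined <- dplyr::inner_join(
    tibble::as_tibble(local), tibble::as_tibble(dist),
    by = c("trial_id", "t_index")
  )
  if (nrow(joined) == 0) stop_tf("no overlapping time indices between series")
  out <- bin_and_smooth(joined$dist_bl, joined$local_bits, span, bin_width_bl)
  names(out)[names(out) == "center"] <- "dist_bl"
  structure(
    out,
    signal = "local_te_bits",
    direction = attr(local, "direction", exact = TRUE),
    pattern = attr(local, "pattern", exact = TRUE),
    span = span, bin_width_bl = bin_width_bl,
    class = c("te_profile", class(tibble::tibble()))
  )
}

#' Speed against pair distance, split by closing/opening gap
#'
#' Speed is the step size divided by the sampling period. Each step is
#' classified by the sign of the distance change over the step (the gap is
#' `increasing` or `decreasing`); a zero change inherits the previous
#' step's class, a leading run of zero changes takes the first signed
#' class that follows (all-zero series default to `increasing`). One
#' binned, LOESS-smoothed profile is returned per role and class.
#'
#' @param data A `tandem_pairs` tibble at the analysis period with
#'   `body_length_mm` set.
#' @param span LOESS span.
#' @param bin_width_bl Bin width in body lengths.
#' @return A tibble of class `te_profile` with columns `role`, `class`,
#'   `dist_bl`, `mean_value` (speed, mm/s), `n`, `smoothed_value`.
#' @export
speed_by_distance <- function(data, span = 0.3, bin_width_bl = 0.1) {
  stopifnot(inherits(data, "tandem_pairs"))
  lens <- dplyr::count(data, .data$trial_id, .data$role)
  if (any(lens$n < 3)) stop_tf("speed classification needs at least 3 positions")
  period <- meta(data, "period_s")
  dist <- pair_distances(data)
  dist_split <- split(dist$dist_mm, dist$trial_id)
  classes <- lapply(dist_split, function(d) {
    chg <- sign(diff(d))
    cls <- ifelse(chg > 0, "increasing", ifelse(chg < 0, "decreasing", NA))
    for (i in seq_along(cls)) if (is.na(cls[i]) && i > 1) cls[i] <- cls[i - 1]
    first_signed <- which(!is.na(cls))[1]
    if (is.na(first_signed)) cls[] <- "increasing"
    else if (first_signed > 1) cls[seq_len(first_signed - 1)] <- cls[first_signed]
    cls
  })
  class_tbl <- tibble::tibble(
    trial_id = rep(names(classes), lengths(classes)),
    t_index = unlist(lapply(dist_split, function(d) seq_len(length(d) - 1)),
                     use.names = FALSE) +
      rep(vapply(split(dist$t_index, dist$trial_id), min, numeric(1)) - 1,
          lengths(classes)),
    gap_class = unlist(classes, use.names = FALSE)
  )
  steps <- step_sizes(data)
  joined <- dplyr::inner_join(steps, class_tbl, by = c("trial_id", "t_index"))
  joined <- dplyr::inner_join(joined, dist[, c("trial_id", "t_index", "dist_bl")],
                              by = c("trial_id", "t_index"))
  joined$speed <- joined$step_mm / period
  profiles <- dplyr::group_modify(
    dplyr::group_by(joined, .data$role, .data$gap_class),
    function(g, key) {
      out <- bin_and_smooth(g$dist_bl, g$speed, span, bin_width_bl)
      names(out)[names(out) == "center"] <- "dist_bl"
      out
    }
  )
  profiles <- dplyr::rename(dplyr::ungroup(profiles), class = "gap_class")
  structure(
    tibble::as_tibble(profiles),
    signal = "speed_mm_s", span = span, bin_width_bl = bin_width_bl,
    class = c("te_profile", class(tibble::tibble()))
  )
}

#' Plot a binned, smoothed distance profile
#'
#' @param object A `te_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_profile
#' @export
autoplot.te_profile <- function(object, ...) {
  has_groups <- all(c("role", "class") %in% names(object))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$dist_bl))
  if (has_groups) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_value,
                                      colour = .data$role,
                                      linetype = .data$class))
  } else {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(y = .data$mean_value, size = .data$n),
                          alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_value),
                         colour = "#762a83", linewidth = 1)
  }
  p +
    ggplot2::labs(
      x = "distance between centroids (body lengths)",
      y = attr(object, "signal", exact = TRUE) %||% "value"
    ) +
    ggplot2::theme_minimal()
}
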