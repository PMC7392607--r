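#' Construct a validated table of paired leader-follower trajectories
#'
#' A tandem-pairs table is the package's canonical trajectory container: one
#' row per animal per retained video frame, with columns `trial_id`, `role`
#' (`"leader"` or `"follower"`), `frame` (original 0-based frame index),
#' `t_index` (1-based position index at the current sampling period), and
#' coordinates `x`, `y` in millimetres. Sampling metadata travel as
#' attributes: `frame_rate` (native frames per second), `period_s` (current
#' sampling period, seconds), `species`, `body_length_mm` (species mean body
#' length, used as the cross-species distance unit), and `y_down` (whether
#' the y axis points downward, the usual image-coordinate convention; this
#' only swaps clockwise/counterclockwise labels, never the information
#' measures themselves).
#'
#' Every trial must contain exactly one leader and one follower track of
#' equal length sampled on the same frames; frames must be consecutive (a
#' gap is a structural error -- tracks are never silently interpolated,
#' which would inject spurious autocorrelation).
#'
#' @param df Data frame with columns `trial_id`, `role`, `frame`, `x`, `y`.
#' @param frame_rate Native sampling rate, frames per second.
#' @param scale_mm_per_px Multiplicative conversion from the stored
#'   coordinate unit to millimetres (1 if already in mm).
#' @param species Optional species label.
#' @param body_length_mm Species mean body length in mm (e.g. 2.34 for
#'   *T. rugatulus*, 8.89 for *C. formosanus*, 5.5 for *R. speratus*).
#' @param y_down Logical; `TRUE` if the y axis increases downward.
#' @return A tibble of class `tandem_pairs` (coordinates in mm).
#' @export
tandem_pairs <- function(df, frame_rate, scale_mm_per_px = 1,
                         species = NA_character_, body_length_mm = NA_real_,
                         y_down = FALSE) {
  required <- c("trial_id", "role", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_structural(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  stopifnot(is.numeric(frame_rate), frame_rate > 0,
            is.numeric(scale_mm_per_px), scale_mm_per_px > 0)
  df <- tibble::as_tibble(df)[required]
  df$trial_id <- as.character(df$trial_id)
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    stop_parse("columns x and y must be numeric")
  }
  if (anyNA(df$x) || anyNA(df$y) || !all(is.finite(df$x) & is.finite(df$y))) {
    stop_parse("non-finite or missing coordinate values")
  }
  bad_role <- setdiff(unique(df$role), c("leader", "follower"))
  if (length(bad_role) > 0) {
    stop_structural(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }

  df <- dplyr::arrange(df, .data$trial_id, .data$role, .data$frame)
  per_track <- dplyr::summarise(
    dplyr::group_by(df, .data$trial_id, .data$role),
    n = dplyr::n(),
    first_frame = .data$frame[1],
    contiguous = all(diff(.data$frame) == 1L) || dplyr::n() == 1L,
    .groups = "drop"
  )
  per_trial <- dplyr::summarise(
    dplyr::group_by(per_track, .data$trial_id),
    n_roles = dplyr::n(),
    has_both = all(c("leader", "follower") %in% .data$role),
    equal_len = dplyr::n_distinct(.data$n) == 1L,
    .groups = "drop"
  )
  if (!all(per_trial$n_roles == 2L & per_trial$has_both)) {
    bad <- per_trial$trial_id[!(per_trial$n_roles == 2L & per_trial$has_both)]
    stop_structural(paste0(
      "each trial needs exactly one leader and one follower track; offending trial(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  if (!all(per_track$contiguous)) {
    stop_structural("non-monotonic or gapped frame indices (tracks are not interpolated)")
  }
  if (!all(per_trial$equal_len)) {
    stop_structural("leader and follower tracks differ in length within a trial")
  }

  df$x <- df$x * scale_mm_per_px
  df$y <- df$y * scale_mm_per_px
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$trial_id, .data$role),
    t_index = dplyr::row_number(),
    .after = "frame"
  )
  df <- dplyr::ungroup(df)

  structure(
    df,
    frame_rate = frame_rate,
    period_s = 1 / frame_rate,
    species = species,
    body_length_mm = body_length_mm,
    y_down = isTRUE(y_down),
    class = c("tandem_pairs", class(tibble::tibble()))
  )
}

#' Read paired trajectories from delimited text
#'
#' Expects one row per animal per frame with columns `trial_id`,
#' `role` (`leader`/`follower`), `frame` (0-based), `x`, `y` (pixels or mm).
#'
#' @param path Path to a CSV (or TSV, auto-detected by readr) file.
#' @param scale_mm_per_px Conversion factor from file units to mm.
#' @param frame_rate Frames per second of the recording.
#' @inheritParams tandem_pairs
#' @return A `tandem_pairs` tibble in millimetres.
#' @seealso [tandem_pairs()] for the validation rules,
#'   [write_tandem_pairs()] for the inverse.
#' @export
read_tandem_pairs <- function(path, scale_mm_per_px, frame_rate,
                              species = NA_character_,
                              body_length_mm = NA_real_, y_down = FALSE) {
  if (!file.exists(path)) stop_tf(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(readr::problems(df)) > 0) {
    stop_parse(paste0("parse failure reading ", path))
  }
  tandem_pairs(df, frame_rate = frame_rate, scale_mm_per_px = scale_mm_per_px,
               species = species, body_length_mm = body_length_mm,
               y_down = y_down)
}

#' Write paired trajectories to CSV (coordinates in mm)
#'
#' @param data A `tandem_pairs` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tandem_pairs <- function(data, path) {
  readr::write_csv(
    data[, c("trial_id", "role", "frame", "x", "y")], path, progress = FALSE
  )
  invisible(path)
}

#' Clip every trial to a fixed duration
#'
#' Keeps the first `floor(duration_s / period_s)` positions of each track at
#' the current sampling period; a 15-min recording at the native 29.97
#' frames/s keeps 26973 positions.
#'
#' @param data A `tandem_pairs` tibble.
#' @param duration_s Duration to keep, seconds.
#' @return The clipped `tandem_pairs` tibble.
#' @export
clip_duration <- function(data, duration_s) {
  stopifnot(inherits(data, "tandem_pairs"), duration_s > 0)
  period <- meta(data, "period_s")
  # tiny epsilon so exact multiples are not lost to floating-point rounding
  n_keep <- floor(duration_s / period + 1e-9)
  lens <- dplyr::count(data, .data$trial_id, .data$role)
  if (any(lens$n < n_keep)) {
    avail <- min(lens$n) * period
    stop_tf(sprintf(
      "requested %.4g s but only %.4g s available in the shortest track",
      duration_s, avail
    ))
  }
  out <- dplyr::filter(data, .data$t_index <= n_keep)
  restore_meta(out, data)
}

#' Temporally subsample trajectories
#'
#' Retains every n-th position (positions n, 2n, 3n, ...), where
#' `n = round(period_s * frame_rate / (period_s_current * frame_rate))`
#' relative to the current period, so a track of N positions keeps
#' `floor(N / n)`. The requested period must be an integer multiple of the
#' current sampling interval within printed (four-decimal) rounding; e.g.
#' 1.5015 s at 29.97 frames/s is 45 native intervals and turns a 900-s
#' track of 26973 positions into 599.
#'
#' @param data A `tandem_pairs` tibble.
#' @param period_s Target sampling period, seconds.
#' @return The subsampled `tandem_pairs` tibble with updated `period_s`.
#' @seealso [expected_sample_count()] for the printed-period count
#'   convention used in cross-study comparisons.
#' @export
subsample_trajectories <- function(data, period_s) {
  stopifnot(inherits(data, "tandem_pairs"), period_s > 0)
  cur <- meta(data, "period_s")
  n <- round(period_s / cur)
  if (n < 1) {
    stop_tf(sprintf(
      "period %.6g s is below the current sampling interval %.6g s",
      period_s, cur
    ))
  }
  if (!same_period(period_s, n * cur)) {
    stop_tf(sprintf(
      "period %.6g s is not an integer multiple of the sampling interval %.6g s",
      period_s, cur
    ))
  }
  if (n == 1) return(data)
  out <- dplyr::filter(data, .data$t_index %% n == 0L)
  out <- dplyr::mutate(out, t_index = .data$t_index %/% n)
  restore_meta(out, data, extra = list(period_s = n * cur))
}

#' Sample count implied by a printed sampling period
#'
#' Cross-study tables report the number of time steps as
#' `floor(duration_s / period_s)` computed with the period printed at four
#' decimals. This can differ by one from actual integer-frame decimation
#' (e.g. 900 s at a printed 0.1668 s gives 5395, while decimating 26973
#' frames by 5 keeps 5394); use this function when comparing against
#' printed counts and [subsample_trajectories()] for the series itself.
#'
#' @param duration_s Recording duration, seconds.
#' @param period_s Printed sampling period, seconds.
#' @return Integer sample count.
#' @export
expected_sample_count <- function(duration_s, period_s) {
  stopifnot(duration_s > 0, period_s > 0)
  as.integer(floor(duration_s / period_s + 1e-9))
}

#' Default sampling-period grid
#'
#' The 45 integer multiples of the native sampling interval, from one frame
#' (33.3667 ms at 29.97 frames/s) up to 45 frames (1.5015 s).
#'
#' @param frame_rate Native frame rate, frames per second.
#' @param n_periods Number of multiples.
#' @return Numeric vector of periods in seconds.
#' @export
default_periods <- function(frame_rate = 29.97, n_periods = 45) {
  seq_len(n_periods) / frame_rate
}

#' @export
print.tandem_pairs <- function(x, ...) {
  cat(sprintf(
    "<tandem_pairs> %d trial(s), period %.4f s, frame rate %.4g/s, species %s\n",
    dplyr::n_distinct(x$trial_id), meta(x, "period_s"),
    meta(x, "frame_rate"), meta(x, "species")
  ))
  NextMethod()
}
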