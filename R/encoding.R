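#' Step sizes of each track
#'
#' The distance travelled between consecutive sampled positions; step
#' `t_index = i` covers the displacement from position i to position i+1,
#' so each track of n positions yields n-1 steps.
#'
#' @param data A `tandem_pairs` tibble.
#' @return Tibble with columns `trial_id`, `role`, `t_index`, `step_mm`.
#' @export
step_sizes <- function(data) {
  stopifnot(inherits(data, "tandem_pairs"))
  lens <- dplyr::count(data, .data$trial_id, .data$role)
  if (any(lens$n < 2)) stop_tf("step sizes need at least 2 positions per track")
  out <- dplyr::reframe(
    dplyr::group_by(data, .data$trial_id, .data$role),
    t_index = .data$t_index[-dplyr::n()],
    step_mm = sqrt(diff(.data$x)^2 + diff(.data$y)^2)
  )
  restore_meta(tibble::as_tibble(out), data)
}

#' Fit the pause/motion step-size threshold
#'
#' The step-size distribution of a tandem-running pair is bimodal: a
#' low-speed mode produced by pauses (plus tracking jitter) and a
#' high-speed mode produced by sustained motion. The threshold separating
#' them is taken as the q-th percentile (default 10) of step sizes pooled
#' over all individuals -- leaders and followers together -- of the dataset
#' at its current sampling period, with linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param data A `tandem_pairs` tibble, already subsampled to the period of
#'   interest.
#' @param q Percentile in `[0, 100]`; default 10.
#' @param pool_roles Pool leaders and followers when fitting (default
#'   `TRUE`); set `FALSE` to fit a separate threshold per role (returns one
#'   row per role).
#' @return A tibble of class `step_threshold` with columns `species`,
#'   `period_s`, `percentile_q`, `threshold_mm` (and `role` when
#'   `pool_roles = FALSE`).
#' @export
pause_threshold <- function(data, q = 10, pool_roles = TRUE) {
  stopifnot(q >= 0, q <= 100)
  sizes <- step_sizes(data)
  if (nrow(sizes) == 0) stop_tf("empty pooled step-size sample")
  if (pool_roles) {
    thr <- tibble::tibble(
      species = meta(data, "species"),
      period_s = meta(data, "period_s"),
      percentile_q = q,
      threshold_mm = unname(stats::quantile(sizes$step_mm, q / 100, type = 7))
    )
  } else {
    thr <- dplyr::summarise(
      dplyr::group_by(sizes, .data$role),
      species = meta(data, "species"),
      period_s = meta(data, "period_s"),
      percentile_q = q,
      threshold_mm = unname(stats::quantile(.data$step_mm, q / 100, type = 7)),
      .groups = "drop"
    )
  }
  class(thr) <- c("step_threshold", class(thr))
  thr
}

new_tandem_symbols <- function(tbl, data, pattern, alphabet, threshold = NULL) {
  tbl <- tibble::as_tibble(tbl)
  tbl <- restore_meta(tbl, data, extra = list(
    pattern = pattern, alphabet = alphabet, threshold = threshold
  ))
  class(tbl) <- c("tandem_symbols", class(tibble::tibble()))
  tbl
}

threshold_for <- function(data, threshold, q) {
  if (is.null(threshold)) threshold <- pause_threshold(data, q = q)
  if (!same_period(threshold$period_s[1], meta(data, "period_s"))) {
    stop_tf(sprintf(
      "threshold fitted at period %.4f s but data sampled at %.4f s",
      threshold$period_s[1], meta(data, "period_s")
    ))
  }
  threshold
}

#' Encode the pausing pattern (binary motion/pause alphabet)
#'
#' Each step is encoded `P` (pause) if its travelled distance is less than
#' or equal to the threshold, `M` (motion) otherwise; ties at the threshold
#' count as pauses. With the threshold fitted at the q-th percentile of the
#' same pooled data, a fraction q/100 of all steps is encoded `P` (up to
#' tie mass). Symbol `t_index = i` describes the step from position i to
#' i+1, so a track of n positions gives n-1 symbols.
#'
#' @param data A `tandem_pairs` tibble at the threshold's sampling period.
#' @param threshold A `step_threshold`, or `NULL` to fit one from `data`.
#' @param q Percentile used when fitting a threshold internally.
#' @return A `tandem_symbols` tibble (columns `trial_id`, `role`,
#'   `t_index`, `symbol`) over the alphabet `{M, P}`.
#' @export
encode_pausing <- function(data, threshold = NULL, q = 10) {
  threshold <- threshold_for(data, threshold, q)
  sizes <- step_sizes(data)
  if ("role" %in% names(threshold)) {
    sizes <- dplyr::left_join(
      sizes, threshold[, c("role", "threshold_mm")], by = "role"
    )
  } else {
    sizes$threshold_mm <- threshold$threshold_mm[1]
  }
  out <- dplyr::mutate(
    sizes,
    symbol = ifelse(.data$step_mm <= .data$threshold_mm, "P", "M"),
    step_mm = NULL, threshold_mm = NULL
  )
  new_tandem_symbols(out, data, "pausing", c("M", "P"), threshold)
}

# CW/CCW labels from one track; exact-zero cross products (collinear or
# stationary steps) copy the previous symbol, a leading collinear run is
# back-filled from the first signed turn
rotation_track <- function(x, y, y_down) {
  n <- length(x)
  if (n < 3) stop_tf("rotation encoding needs at least 3 positions")
  dx <- diff(x)
  dy <- diff(y)
  cr <- dx[-(n - 1)] * dy[-1] - dy[-(n - 1)] * dx[-1]
  if (y_down) cr <- -cr
  sym <- rep(NA_character_, n - 2)
  sym[cr > 0] <- "CCW"
  sym[cr < 0] <- "CW"
  if (all(is.na(sym))) stop_tf("entire track is collinear; no turn direction defined")
  # carry forward, then back-fill the initial run
  filled <- sym
  for (i in seq_along(filled)) {
    if (is.na(filled[i]) && i > 1) filled[i] <- filled[i - 1]
  }
  first_signed <- which(!is.na(sym))[1]
  if (first_signed > 1) filled[seq_len(first_signed - 1)] <- sym[first_signed]
  filled
}

#' Encode the rotation pattern (binary turn-direction alphabet)
#'
#' The turn direction at interior position i is the sign of the 2-D cross
#' product of the displacement into i with the displacement out of i:
#' positive is counterclockwise (`CCW`), negative clockwise (`CW`) in a
#' y-up coordinate frame (labels swap when the data carry `y_down = TRUE`).
#' An exactly zero cross product (collinear or stationary motion) copies
#' the previous time step's direction; a collinear run at the start of a
#' track takes the first signed direction that follows. A fully collinear
#' track is an error. Symbol `t_index = i` uses positions i-1, i, i+1, so a
#' track of n positions gives n-2 symbols indexed 2..n-1.
#'
#' @param data A `tandem_pairs` tibble.
#' @return A `tandem_symbols` tibble over the alphabet `{CW, CCW}`.
#' @export
encode_rotation <- function(data) {
  stopifnot(inherits(data, "tandem_pairs"))
  y_down <- isTRUE(meta(data, "y_down"))
  out <- dplyr::reframe(
    dplyr::group_by(data, .data$trial_id, .data$role),
    t_index = .data$t_index[c(-1, -dplyr::n())],
    symbol = rotation_track(.data$x, .data$y, y_down)
  )
  new_tandem_symbols(out, data, "rotation", c("CW", "CCW"))
}

#' Encode the compound pausing-and-rotation pattern (ternary alphabet)
#'
#' Pauses are mutually exclusive with rotations: wherever the pausing
#' encoder yields `P` the compound symbol is `P` regardless of the turn
#' geometry; every other time step takes its rotation symbol. The two
#' constituent series are aligned by dropping leading entries to the common
#' index range 2..n-1.
#'
#' @inheritParams encode_pausing
#' @return A `tandem_symbols` tibble over the alphabet `{P, CW, CCW}`.
#' @export
encode_compound <- function(data, threshold = NULL, q = 10) {
  threshold <- threshold_for(data, threshold, q)
  pausing <- encode_pausing(data, threshold = threshold)
  rotation <- encode_rotation(data)
  joined <- dplyr::inner_join(
    rotation,
    dplyr::rename(pausing, pause_symbol = "symbol"),
    by = c("trial_id", "role", "t_index")
  )
  out <- dplyr::mutate(
    joined,
    symbol = ifelse(.data$pause_symbol == "P", "P", .data$symbol),
    pause_symbol = NULL
  )
  new_tandem_symbols(out, data, "compound", c("P", "CW", "CCW"), threshold)
}

#' Encode a behavioral pattern by name
#'
#' @inheritParams encode_pausing
#' @param pattern One of `"pausing"`, `"rotation"`, `"compound"`.
#' @return A `tandem_symbols` tibble.
#' @export
encode_pattern <- function(data, pattern = c("pausing", "rotation", "compound"),
                           threshold = NULL, q = 10) {
  pattern <- match.arg(pattern)
  switch(pattern,
    pausing = encode_pausing(data, threshold, q),
    rotation = encode_rotation(data),
    compound = encode_compound(data, threshold, q)
  )
}

#' Write / read symbol series as delimited text
#'
#' One row per time step with columns `trial_id`, `role`, `t_index`,
#' `symbol`; the round trip is bit-exact.
#'
#' @param symbols A `tandem_symbols` tibble.
#' @param path File path.
#' @return `path` (writer) or a `tandem_symbols` tibble (reader); the
#'   reader takes `pattern` and `period_s` to restore metadata.
#' @export
write_symbols <- function(symbols, path) {
  stopifnot(inherits(symbols, "tandem_symbols"))
  readr::write_csv(
    symbols[, c("trial_id", "role", "t_index", "symbol")], path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_symbols
#' @param pattern Pattern name the series was encoded with.
#' @param period_s Sampling period of the series, seconds.
#' @export
read_symbols <- function(path, pattern = c("pausing", "rotation", "compound"),
                         period_s = NA_real_) {
  pattern <- match.arg(pattern)
  tbl <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      trial_id = readr::col_character(), role = readr::col_character(),
      t_index = readr::col_integer(), symbol = readr::col_character()
    )
  )
  alphabet <- switch(pattern,
    pausing = c("M", "P"), rotation = c("CW", "CCW"),
    compound = c("P", "CW", "CCW")
  )
  bad <- setdiff(unique(tbl$symbol), alphabet)
  if (length(bad) > 0) {
    stop_parse(paste0("symbols outside alphabet: ", paste(bad, collapse = ", ")))
  }
  out <- tibble::as_tibble(tbl)
  attr(out, "pattern") <- pattern
  attr(out, "alphabet") <- alphabet
  attr(out, "period_s") <- period_s
  class(out) <- c("tandem_symbols", class(tibble::tibble()))
  out
}

#' @export
print.tandem_symbols <- function(x, ...) {
  cat(sprintf(
    "<tandem_symbols> pattern %s, alphabet {%s}, period %.4f s\n",
    meta(x, "pattern"), paste(meta(x, "alphabet"), collapse = ","),
    meta(x, "period_s") %||% NA_real_
  ))
  NextMethod()
}
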