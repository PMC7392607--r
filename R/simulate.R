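#' Configuration of a synthetic leader-follower communication protocol
#'
#' Builds the parameter set of the coupled-walker generator. Three
#' protocols with known ground-truth information-flow directions are
#' provided:
#'
#' * `"ant"`: the leader turns persistently and drives the route
#'   (rotation flow leader to follower) while the *follower* initiates
#'   search pauses; the resulting separations make the leader stop once
#'   the gap exceeds `d_stop_bl` body lengths and resume once the follower
#'   has closed it below `d_go_bl` (pausing flow follower to leader).
#' * `"termite"`: the leader both drives the route and pauses
#'   spontaneously; the pursuing follower halts at contact distance when
#'   the leader halts (both flows leader to follower).
#' * `"independent"`: two uncoupled persistent walkers with spontaneous
#'   pauses (no information flow in either direction).
#'
#' Defaults emulate the recorded study conditions: 29.97 frames/s
#' sampling, 15-minute trials, millimetre coordinates, species-scale body
#' lengths (2.34 mm ant, 8.89 mm termite) and speeds, and centroid
#' tracking jitter that makes the step-size distribution bimodal (a pause
#' mode near the jitter scale and a motion mode near speed times sampling
#' interval).
#'
#' @param mode Protocol name.
#' @param frame_rate Frames per second.
#' @param duration_s Trial duration, seconds.
#' @param body_length_mm Body length, mm.
#' @param leader_speed_mm_s,follower_speed_mm_s Walking speeds, mm/s (the
#'   follower is faster, so it can close gaps in pursuit modes).
#' @param turn_rate_deg_s Magnitude of the leader's biased turning, deg/s.
#' @param turn_switch_rate_s Rate of the two-state (clockwise /
#'   counterclockwise) turn-direction Markov chain switching sign, per
#'   second; its inverse is the turn persistence time.
#' @param leader_heading_noise_deg Diffusive heading noise of the leader,
#'   deg per square-root second.
#' @param heading_noise_deg Follower aiming noise around the bearing to
#'   the leader, deg (per step).
#' @param follower_pause_rate_s Rate at which the follower starts a search
#'   pause, per second (ant protocol).
#' @param pause_duration_mean_s Mean duration of follower search pauses,
#'   seconds (geometric bout lengths).
#' @param leader_pause_rate_s Rate of spontaneous leader pauses, per
#'   second (termite and independent protocols).
#' @param leader_pause_duration_mean_s Mean leader pause duration, s.
#' @param d_stop_bl,d_go_bl Leader stop/resume distance thresholds in body
#'   lengths (ant protocol; `d_go_bl < d_stop_bl` gives hysteresis).
#' @param contact_dist_bl Pursuit standoff: the follower never moves
#'   closer than this many body lengths from the leader centroid.
#' @param jitter_mm Centroid tracking noise (Gaussian sd per coordinate),
#'   mm.
#' @param arena_mm Width/height of the reflective arena rectangle, mm.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(mode = c("ant", "termite", "independent"),
                            frame_rate = 29.97,
                            duration_s = 900,
                            body_length_mm = NULL,
                            leader_speed_mm_s = NULL,
                            follower_speed_mm_s = NULL,
                            turn_rate_deg_s = 60,
                            turn_switch_rate_s = 0.5,
                            leader_heading_noise_deg = 30,
                            heading_noise_deg = 15,
                            follower_pause_rate_s = NULL,
                            pause_duration_mean_s = 4,
                            leader_pause_rate_s = NULL,
                            leader_pause_duration_mean_s = 1.5,
                            d_stop_bl = 3,
                            d_go_bl = 1.5,
                            contact_dist_bl = 0.5,
                            jitter_mm = NULL,
                            arena_mm = NULL) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    frame_rate = frame_rate,
    duration_s = duration_s,
    body_length_mm = body_length_mm %||%
      switch(mode, ant = 2.34, termite = 8.89, independent = 2.34),
    leader_speed_mm_s = leader_speed_mm_s %||%
      switch(mode, ant = 2, termite = 10, independent = 2),
    follower_speed_mm_s = follower_speed_mm_s %||%
      switch(mode, ant = 2.6, termite = 12, independent = 2),
    turn_rate_deg_s = turn_rate_deg_s,
    turn_switch_rate_s = turn_switch_rate_s,
    leader_heading_noise_deg = leader_heading_noise_deg,
    heading_noise_deg = heading_noise_deg,
    follower_pause_rate_s = follower_pause_rate_s %||%
      switch(mode, ant = 0.05, termite = 0, independent = 0.05),
    pause_duration_mean_s = pause_duration_mean_s,
    leader_pause_rate_s = leader_pause_rate_s %||%
      switch(mode, ant = 0, termite = 0.1, independent = 0.05),
    leader_pause_duration_mean_s = leader_pause_duration_mean_s,
    d_stop_bl = d_stop_bl,
    d_go_bl = d_go_bl,
    contact_dist_bl = contact_dist_bl,
    jitter_mm = jitter_mm %||%
      switch(mode, ant = 0.05, termite = 0.1, independent = 0.05),
    arena_mm = arena_mm %||%
      switch(mode, ant = c(370, 655), termite = c(145, 145),
             independent = c(370, 655))
  )
  stopifnot(
    cfg$frame_rate > 0, cfg$duration_s > 0, cfg$body_length_mm > 0,
    cfg$leader_speed_mm_s > 0, cfg$follower_speed_mm_s > 0,
    cfg$follower_pause_rate_s >= 0, cfg$follower_pause_rate_s <= 1 * cfg$frame_rate,
    cfg$leader_pause_rate_s >= 0,
    cfg$d_go_bl < cfg$d_stop_bl,
    cfg$jitter_mm >= 0, length(cfg$arena_mm) == 2, all(cfg$arena_mm > 0)
  )
  class(cfg) <- "protocol_config"
  cfg
}

# reflect a proposed position into [0, w] x [0, h]; returns position and
# whether a boundary was hit
reflect1 <- function(z, w) {
  if (z < 0) return(-z)
  if (z > w) return(2 * w - z)
  z
}

#' Simulate one leader-follower trajectory pair
#'
#' Frame-by-frame update of the two coupled walkers under the protocol in
#' `config` (see [protocol_config()] for the dynamics). Emitted positions
#' include centroid tracking jitter; everything is reproducible from the
#' seed.
#'
#' @param config A `protocol_config`.
#' @param seed Integer seed.
#' @param trial_id Trial identifier for the output table.
#' @return A `tandem_pairs` tibble (species `"synthetic-<mode>"`).
#' @export
simulate_tandem_pair <- function(config, seed, trial_id = "pair01") {
  stopifnot(inherits(config, "protocol_config"))
  set.seed(seed)
  dt <- 1 / config$frame_rate
  n <- floor(config$duration_s / dt + 1e-9)
  bl <- config$body_length_mm
  arena <- config$arena_mm

  # pre-drawn randomness (loop consumes scalars from these vectors)
  turn_flip_l <- stats::runif(n) < config$turn_switch_rate_s * dt
  head_noise_l <- stats::rnorm(n, 0, config$leader_heading_noise_deg *
                                 pi / 180 * sqrt(dt))
  pause_u_l <- stats::runif(n)
  unpause_u_l <- stats::runif(n)
  pause_u_f <- stats::runif(n)
  unpause_u_f <- stats::runif(n)
  aim_noise_f <- stats::rnorm(n, 0, config$heading_noise_deg * pi / 180)
  turn_flip_f <- stats::runif(n) < config$turn_switch_rate_s * dt
  head_noise_f <- stats::rnorm(n, 0, config$leader_heading_noise_deg *
                                 pi / 180 * sqrt(dt))

  p_pause_l <- config$leader_pause_rate_s * dt
  p_unpause_l <- if (config$leader_pause_duration_mean_s > 0)
    dt / config$leader_pause_duration_mean_s else 1
  p_pause_f <- config$follower_pause_rate_s * dt
  p_unpause_f <- if (config$pause_duration_mean_s > 0)
    dt / config$pause_duration_mean_s else 1
  v_l <- config$leader_speed_mm_s * dt
  v_f <- config$follower_speed_mm_s * dt
  d_stop <- config$d_stop_bl * bl
  d_go <- config$d_go_bl * bl
  d_contact <- config$contact_dist_bl * bl
  independent <- identical(config$mode, "independent")
  ant <- identical(config$mode, "ant")

  lx <- ly <- fx <- fy <- numeric(n)
  lx[1] <- arena[1] / 2
  ly[1] <- arena[2] / 2
  heading_l <- stats::runif(1, 0, 2 * pi)
  if (independent) {
    # uncoupled walkers share nothing, including initial conditions
    heading_f <- stats::runif(1, 0, 2 * pi)
    fx[1] <- lx[1] - cos(heading_f) * bl
    fy[1] <- ly[1] - sin(heading_f) * bl
  } else {
    # the follower starts in tandem position, one body length behind
    fx[1] <- lx[1] - cos(heading_l) * bl
    fy[1] <- ly[1] - sin(heading_l) * bl
    heading_f <- heading_l
  }
  s_l <- sample(c(-1, 1), 1)
  s_f <- sample(c(-1, 1), 1)
  paused_l <- FALSE
  paused_f <- FALSE
  turn_step <- config$turn_rate_deg_s * pi / 180 * dt

  for (i in seq_len(n - 1)) {
    gap_x <- lx[i] - fx[i]
    gap_y <- ly[i] - fy[i]
    dist <- sqrt(gap_x^2 + gap_y^2)

    # leader pause state
    if (ant) {
      if (!paused_l && dist > d_stop) paused_l <- TRUE
      else if (paused_l && dist < d_go) paused_l <- FALSE
    } else {
      if (!paused_l) paused_l <- pause_u_l[i] < p_pause_l
      else if (unpause_u_l[i] < p_unpause_l) paused_l <- FALSE
    }

    # leader heading and advance
    if (turn_flip_l[i]) s_l <- -s_l
    heading_l <- heading_l + s_l * turn_step + head_noise_l[i]
    if (!paused_l) {
      nx <- lx[i] + v_l * cos(heading_l)
      ny <- ly[i] + v_l * sin(heading_l)
      rx <- reflect1(nx, arena[1])
      ry <- reflect1(ny, arena[2])
      if (rx != nx) heading_l <- pi - heading_l
      if (ry != ny) heading_l <- -heading_l
      lx[i + 1] <- rx
      ly[i + 1] <- ry
    } else {
      lx[i + 1] <- lx[i]
      ly[i + 1] <- ly[i]
    }

    # follower
    if (independent) {
      if (!paused_f) paused_f <- pause_u_f[i] < p_pause_l
      else if (unpause_u_f[i] < p_unpause_l) paused_f <- FALSE
      if (turn_flip_f[i]) s_f <- -s_f
      heading_f <- heading_f + s_f * turn_step + head_noise_f[i]
      if (!paused_f) {
        nx <- fx[i] + v_l * cos(heading_f)
        ny <- fy[i] + v_l * sin(heading_f)
        rx <- reflect1(nx, arena[1])
        ry <- reflect1(ny, arena[2])
        if (rx != nx) heading_f <- pi - heading_f
        if (ry != ny) heading_f <- -heading_f
        fx[i + 1] <- rx
        fy[i + 1] <- ry
      } else {
        fx[i + 1] <- fx[i]
        fy[i + 1] <- fy[i]
      }
    } else {
      # pursuit: search pauses (ant) and contact standoff
      if (ant) {
        if (!paused_f) paused_f <- pause_u_f[i] < p_pause_f
        else if (unpause_u_f[i] < p_unpause_f) paused_f <- FALSE
      }
      if (paused_f) {
        fx[i + 1] <- fx[i]
        fy[i + 1] <- fy[i]
      } else {
        bearing <- atan2(ly[i] - fy[i], lx[i] - fx[i]) + aim_noise_f[i]
        step_len <- min(v_f, max(0, dist - d_contact))
        fx[i + 1] <- fx[i] + step_len * cos(bearing)
        fy[i + 1] <- fy[i] + step_len * sin(bearing)
      }
    }
  }

  obs_noise <- stats::rnorm(4 * n, 0, config$jitter_mm)
  df <- tibble::tibble(
    trial_id = trial_id,
    role = rep(c("leader", "follower"), each = n),
    frame = rep(0:(n - 1), 2),
    x = c(lx + obs_noise[1:n], fx + obs_noise[(2 * n + 1):(3 * n)]),
    y = c(ly + obs_noise[(n + 1):(2 * n)], fy + obs_noise[(3 * n + 1):(4 * n)])
  )
  tandem_pairs(df, frame_rate = config$frame_rate,
               species = paste0("synthetic-", config$mode),
               body_length_mm = bl, y_down = FALSE)
}

#' Simulate a dataset of independent tandem pairs
#'
#' Per-pair seeds are drawn once from the master seed
#' (`sample.int(.Machine$integer.max - 1, n_pairs)` after
#' `set.seed(seed)`), so any single pair can be re-simulated exactly from
#' its recorded seed. The per-pair seeds are stored in the `pair_seeds`
#' attribute.
#'
#' @inheritParams simulate_tandem_pair
#' @param n_pairs Number of pairs (at least 2, so surrogate re-pairing is
#'   possible).
#' @return A `tandem_pairs` tibble with trials `pair01`, `pair02`, ...
#' @export
simulate_tandem_dataset <- function(config, n_pairs, seed) {
  stopifnot(inherits(config, "protocol_config"))
  if (n_pairs < 2) stop_tf("a dataset needs at least 2 pairs (surrogates require re-pairing)")
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1, n_pairs)
  pieces <- purrr::map(seq_len(n_pairs), function(i) {
    simulate_tandem_pair(config, seed = pair_seeds[i],
                         trial_id = sprintf("pair%02d", i))
  })
  out <- dplyr::bind_rows(pieces)
  out <- restore_meta(tibble::as_tibble(out), pieces[[1]])
  attr(out, "pair_seeds") <- pair_seeds
  attr(out, "master_seed") <- as.integer(seed)
  class(out) <- class(pieces[[1]])
  out
}

#' Ground-truth information-flow directions of a protocol
#'
#' @param config A `protocol_config` (or a mode name).
#' @return Tibble with columns `pattern` (`rotation`, `pausing`) and
#'   `expected_sign` of net transfer entropy (+1 leader to follower, -1
#'   follower to leader, 0 none).
#' @export
ground_truth <- function(config) {
  mode <- if (inherits(config, "protocol_config")) config$mode else config
  mode <- match.arg(mode, c("ant", "termite", "independent"))
  signs <- switch(mode,
    ant = c(rotation = 1, pausing = -1),
    termite = c(rotation = 1, pausing = 1),
    independent = c(rotation = 0, pausing = 0)
  )
  tibble::tibble(pattern = names(signs), expected_sign = unname(signs))
}
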