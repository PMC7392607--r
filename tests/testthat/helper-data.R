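# fixture builders shared across the suite (everything generated in code)

# assemble a tandem_symbols tibble from raw leader/follower symbol vectors
make_symbols <- function(leader, follower, alphabet, pattern = "pausing",
                         period_s = 1, trial_id = "t1") {
  stopifnot(length(leader) == length(follower))
  tbl <- tibble::tibble(
    trial_id = trial_id,
    role = rep(c("leader", "follower"), each = length(leader)),
    t_index = rep(seq_along(leader), 2),
    symbol = c(as.character(leader), as.character(follower))
  )
  attr(tbl, "pattern") <- pattern
  attr(tbl, "alphabet") <- alphabet
  attr(tbl, "period_s") <- period_s
  class(tbl) <- c("tandem_symbols", class(tibble::tibble()))
  tbl
}

# several trials: leaders / followers are lists of equal-length vectors
make_symbols_multi <- function(leaders, followers, alphabet,
                               pattern = "pausing", period_s = 1) {
  pieces <- lapply(seq_along(leaders), function(i) {
    make_symbols(leaders[[i]], followers[[i]], alphabet, pattern, period_s,
                 trial_id = sprintf("t%02d", i))
  })
  out <- dplyr::bind_rows(pieces)
  for (a in c("pattern", "alphabet", "period_s")) {
    attr(out, a) <- attr(pieces[[1]], a, exact = TRUE)
  }
  class(out) <- c("tandem_symbols", class(tibble::tibble()))
  out
}

# binary M/P recoding of a 0/1 vector
mp <- function(bits) c("M", "P")[bits + 1]

# a tandem_pairs table from explicit leader/follower coordinate matrices
make_pairs <- function(leader_xy, follower_xy = NULL, frame_rate = 1,
                       trial_id = "t1", species = "testium",
                       body_length_mm = 1, y_down = FALSE) {
  if (is.null(follower_xy)) follower_xy <- leader_xy + 0.5
  n <- nrow(leader_xy)
  df <- tibble::tibble(
    trial_id = trial_id,
    role = rep(c("leader", "follower"), each = n),
    frame = rep(0:(n - 1), 2),
    x = c(leader_xy[, 1], follower_xy[, 1]),
    y = c(leader_xy[, 2], follower_xy[, 2])
  )
  tandem_pairs(df, frame_rate = frame_rate, species = species,
               body_length_mm = body_length_mm, y_down = y_down)
}

# random-walk pair table with several trials (smooth enough that exact
# collinearity never occurs)
random_pairs <- function(n_trials = 2, n_frames = 200, frame_rate = 10,
                         seed = 42, body_length_mm = 2) {
  set.seed(seed)
  pieces <- lapply(seq_len(n_trials), function(t) {
    lead <- cbind(cumsum(rnorm(n_frames)), cumsum(rnorm(n_frames)))
    fol <- cbind(cumsum(rnorm(n_frames)), cumsum(rnorm(n_frames))) + 5
    tibble::tibble(
      trial_id = sprintf("t%02d", t),
      role = rep(c("leader", "follower"), each = n_frames),
      frame = rep(0:(n_frames - 1), 2),
      x = c(lead[, 1], fol[, 1]),
      y = c(lead[, 2], fol[, 2])
    )
  })
  tandem_pairs(dplyr::bind_rows(pieces), frame_rate = frame_rate,
               species = "testium", body_length_mm = body_length_mm)
}

# iid-symbol null dataset over {M, P}: leader and follower independent
null_symbol_dataset <- function(n_trials = 20, len = 300, p = 0.5) {
  leaders <- replicate(n_trials, mp(rbinom(len, 1, p)), simplify = FALSE)
  followers <- replicate(n_trials, mp(rbinom(len, 1, p)), simplify = FALSE)
  make_symbols_multi(leaders, followers, alphabet = c("M", "P"))
}
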