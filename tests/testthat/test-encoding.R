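test_that("step sizes are Euclidean distances between consecutive positions", {
  dat <- make_pairs(rbind(c(0, 0), c(3, 4)), rbind(c(0, 0), c(0, 0)))
  s <- step_sizes(dat)
  expect_equal(dplyr::filter(s, role == "leader")$step_mm, 5)
  expect_equal(dplyr::filter(s, role == "follower")$step_mm, 0)

  dat3 <- make_pairs(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(dplyr::filter(step_sizes(dat3), role == "leader")$step_mm, c(1, 1))

  expect_error(step_sizes(make_pairs(rbind(c(0, 0)))), "2 positions")
})

test_that("pause threshold is the interpolated pooled percentile", {
  # ten steps per role: leader carries the two tiny steps
  lead <- rbind(c(0, 0), c(0.01, 0), c(0.02, 0), matrix(cumsum(rep(1, 8)) + 0.02,
                ncol = 1) |> cbind(0))
  fol <- cbind(cumsum(rep(1, 11)), 0)
  dat <- make_pairs(lead, fol)
  thr <- pause_threshold(dat, q = 10)
  # pooled sample: two steps of 0.01 and eighteen of 1.0
  expect_s3_class(thr, "step_threshold")
  expect_gt(thr$threshold_mm, 0.01)
  expect_lt(thr$threshold_mm, 1)
  sym <- encode_pausing(dat, thr)
  expect_equal(sum(sym$symbol == "P"), 2)

  # all-equal step sizes collapse the threshold onto that size
  dat_eq <- make_pairs(cbind(cumsum(rep(2, 6)), 0))
  thr_eq <- pause_threshold(dat_eq, q = 10)
  expect_equal(thr_eq$threshold_mm, 2)
  # ties at the threshold are encoded as pauses
  expect_true(all(encode_pausing(dat_eq, thr_eq)$symbol == "P"))

  # q = 0 gives the minimum
  expect_equal(pause_threshold(dat, q = 0)$threshold_mm, 0.01)
})

test_that("the pooled pause fraction matches the fitted percentile", {
  set.seed(7)
  dat <- random_pairs(n_trials = 3, n_frames = 700)
  sym <- encode_pausing(dat, q = 10)
  expect_equal(mean(sym$symbol == "P"), 0.1, tolerance = 0.01)
  # and at another percentile
  sym15 <- encode_pausing(dat, q = 15)
  expect_equal(mean(sym15$symbol == "P"), 0.15, tolerance = 0.01)
})

test_that("turn directions follow the cross-product sign with carry-forward", {
  left <- make_pairs(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(dplyr::filter(encode_rotation(left), role == "leader")$symbol,
               "CCW")
  right <- make_pairs(rbind(c(0, 0), c(1, 0), c(1, -1)))
  expect_equal(dplyr::filter(encode_rotation(right), role == "leader")$symbol,
               "CW")

  # collinear continuation copies the previous direction
  carry <- make_pairs(rbind(c(0, 0), c(1, 0), c(1, -1), c(1, -2)))
  expect_equal(dplyr::filter(encode_rotation(carry), role == "leader")$symbol,
               c("CW", "CW"))

  # an initial collinear run takes the first signed turn retroactively
  lead_in <- make_pairs(rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1)))
  expect_equal(dplyr::filter(encode_rotation(lead_in), role == "leader")$symbol,
               c("CCW", "CCW"))

  # fully collinear tracks have no defined turn direction
  flat <- make_pairs(cbind(1:5, 0))
  expect_error(encode_rotation(flat), "collinear")

  # image-style coordinates (y down) swap the labels globally
  left_down <- make_pairs(rbind(c(0, 0), c(1, 0), c(1, 1)), y_down = TRUE)
  expect_equal(dplyr::filter(encode_rotation(left_down), role == "leader")$symbol,
               "CW")
})

test_that("rotation encoding is invariant under rigid motions and scaling", {
  set.seed(11)
  dat <- random_pairs(n_trials = 1, n_frames = 120)
  base <- encode_rotation(dat)$symbol

  a <- 0.83
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  xy <- as.matrix(dat[, c("x", "y")]) %*% rot
  moved <- dat
  moved$x <- 3 * xy[, 1] + 17
  moved$y <- 3 * xy[, 2] - 4
  expect_equal(encode_rotation(moved)$symbol, base)

  # reflection flips every label
  mirrored <- dat
  mirrored$y <- -mirrored$y
  flipped <- encode_rotation(mirrored)$symbol
  expect_equal(flipped, ifelse(base == "CW", "CCW", "CW"))
})

test_that("pausing encoding is rigid-motion invariant and scale equivariant", {
  set.seed(13)
  dat <- random_pairs(n_trials = 1, n_frames = 150)
  thr <- pause_threshold(dat, q = 10)
  base <- encode_pausing(dat, thr)$symbol

  moved <- dat
  moved$x <- dat$y + 5
  moved$y <- -dat$x
  expect_equal(encode_pausing(moved, thr)$symbol, base)

  scaled <- dat
  scaled$x <- 2.5 * dat$x
  scaled$y <- 2.5 * dat$y
  thr2 <- thr
  thr2$threshold_mm <- 2.5 * thr$threshold_mm
  expect_equal(encode_pausing(scaled, thr2)$symbol, base)
})

test_that("compound encoding overlays pauses on the rotation stream", {
  set.seed(17)
  dat <- random_pairs(n_trials = 2, n_frames = 200)
  thr <- pause_threshold(dat, q = 10)
  comp <- encode_compound(dat, thr)
  paus <- encode_pausing(dat, thr)
  rota <- encode_rotation(dat)

  joined <- dplyr::inner_join(
    dplyr::rename(comp, compound = symbol),
    dplyr::rename(paus, pausing = symbol),
    by = c("trial_id", "role", "t_index")
  )
  joined <- dplyr::inner_join(
    joined, dplyr::rename(rota, rotation = symbol),
    by = c("trial_id", "role", "t_index")
  )
  # pauses dominate; elsewhere the compound equals the rotation stream
  expect_true(all(joined$compound[joined$pausing == "P"] == "P"))
  expect_equal(joined$compound[joined$pausing != "P"],
               joined$rotation[joined$pausing != "P"])
  # alignment drops the leading entries only
  expect_equal(range(dplyr::filter(comp, trial_id == "t01",
                                   role == "leader")$t_index), c(2, 199))

  # with no sub-threshold step the compound reduces to the rotation stream
  thr0 <- thr
  thr0$threshold_mm <- -1
  comp0 <- encode_compound(dat, thr0)
  expect_equal(comp0$symbol, rota$symbol)
})

test_that("a hand-traced six-point track combines both encoders correctly", {
  # steps: 0.005, 1, 0.005, 1, 0.005 -> pausing P,M,P,M,P (threshold 0.01);
  # geometry alternates right-angle turns
  pts <- rbind(c(0, 0), c(0.005, 0), c(1.005, 0), c(1.005, 0.005),
               c(1.005, 1.005), c(1.01, 1.005))
  dat <- make_pairs(pts)
  thr <- pause_threshold(dat, q = 10)
  thr$threshold_mm <- 0.01
  comp <- dplyr::filter(encode_compound(dat, thr), role == "leader")
  paus <- dplyr::filter(encode_pausing(dat, thr), role == "leader")
  expect_equal(paus$symbol, c("P", "M", "P", "M", "P"))
  # rotation trace: collinear lead-in backfilled CCW, CCW, carried CCW, CW;
  # pauses at t = 3 and 5 overwrite the turns
  expect_equal(comp$t_index, 2:5)
  expect_equal(comp$symbol, c("CCW", "P", "CCW", "P"))
})

test_that("symbol series round-trip through the text writer bit-exactly", {
  set.seed(19)
  dat <- random_pairs(n_trials = 2, n_frames = 100)
  sym <- encode_compound(dat, q = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_symbols(sym, path)
  back <- read_symbols(path, pattern = "compound",
                       period_s = attr(sym, "period_s", exact = TRUE))
  expect_equal(back$symbol, sym$symbol)
  expect_equal(back$t_index, sym$t_index)
  expect_equal(back$trial_id, sym$trial_id)

  # foreign symbols are rejected
  writeLines("trial_id,role,t_index,symbol\na,leader,1,XX", path)
  expect_error(read_symbols(path, "pausing"), class = "tandemflow_parse_error")
})

test_that("period mismatch between data and threshold is caught", {
  dat <- random_pairs(n_trials = 1, n_frames = 200)
  thr <- pause_threshold(dat, q = 10)
  sub <- subsample_trajectories(dat, 0.5)
  expect_error(encode_pausing(sub, thr), "period")
})
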