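test_that("shannon entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.25, 0.75)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum")
})

test_that("conditional entropy matches brute-force enumeration", {
  # M,M,P,M with k=1: three transitions, the M-branch splits 1/1
  sym <- make_symbols(mp(c(0, 0, 1, 0)), mp(c(0, 0, 0, 0)), c("M", "P"))
  expect_equal(conditional_entropy(sym, "leader", k = 1), 2 / 3)

  # strictly alternating series is fully self-predictable at k=1
  alt <- make_symbols(rep(c("CW", "CCW"), 10), rep("CW", 20), c("CW", "CCW"),
                      pattern = "rotation")
  expect_equal(conditional_entropy(alt, "leader", k = 1), 0)

  # iid fair binary approaches 1 bit
  set.seed(3)
  iid <- make_symbols(mp(rbinom(6000, 1, 0.5)), mp(rbinom(6000, 1, 0.5)),
                      c("M", "P"))
  expect_equal(conditional_entropy(iid, "leader", k = 1), 1, tolerance = 0.01)

  # and against the dense oracle on random ternary data
  set.seed(4)
  for (k in 1:3) {
    f <- sample(c("P", "CW", "CCW"), 40, replace = TRUE)
    sym3 <- make_symbols(f, f, c("P", "CW", "CCW"), pattern = "compound")
    expect_equal(conditional_entropy(sym3, "leader", k = k),
                 oracle_cond_entropy(list(f), k, c("P", "CW", "CCW")),
                 tolerance = 1e-12)
  }
})

test_that("plug-in transfer entropy equals the dense-enumeration oracle", {
  set.seed(5)
  alphabets <- list(c("M", "P"), c("P", "CW", "CCW"))
  for (rep_i in 1:12) {
    alphabet <- alphabets[[1 + rep_i %% 2]]
    k <- 1 + rep_i %% 3
    n_trials <- 1 + rep_i %% 2
    lens <- sample((k + 2):12, n_trials, replace = TRUE)
    leaders <- lapply(lens, function(n) sample(alphabet, n, replace = TRUE))
    followers <- lapply(lens, function(n) sample(alphabet, n, replace = TRUE))
    sym <- make_symbols_multi(leaders, followers, alphabet)
    te <- transfer_entropy(sym, "leader", "follower", k = k)
    expect_equal(te$te_bits, oracle_te(leaders, followers, k, alphabet),
                 tolerance = 1e-12)
    # the entropy-difference identity, both sides enumerated independently
    expect_equal(te$te_bits,
                 oracle_cond_entropy(followers, k, alphabet) -
                   oracle_cond_entropy_src(leaders, followers, k, alphabet),
                 tolerance = 1e-12)
    expect_equal(te$cond_entropy_bits,
                 oracle_cond_entropy(followers, k, alphabet),
                 tolerance = 1e-12)
  }
})

test_that("the worked five-symbol example matches the oracle", {
  src <- mp(c(0, 1, 0, 1, 1))
  dst <- mp(c(1, 0, 1, 0, 1))
  sym <- make_symbols(src, dst, c("M", "P"))
  te <- transfer_entropy(sym, "leader", "follower", k = 1)
  expect_equal(te$te_bits, oracle_te(list(src), list(dst), 1, c("M", "P")),
               tolerance = 1e-12)
})

test_that("information bounds hold on arbitrary inputs", {
  set.seed(6)
  for (i in 1:20) {
    alphabet <- if (i %% 2) c("M", "P") else c("P", "CW", "CCW")
    n <- sample(20:80, 1)
    k <- sample(1:4, 1)
    sym <- make_symbols(sample(alphabet, n, replace = TRUE, prob = seq_along(alphabet)),
                        sample(alphabet, n, replace = TRUE), alphabet)
    te <- transfer_entropy(sym, "leader", "follower", k = k)
    expect_gte(te$te_bits, 0)
    expect_lte(te$te_bits, te$cond_entropy_bits + 1e-12)
    expect_lte(te$cond_entropy_bits, log2(length(alphabet)) + 1e-12)
  }
})

test_that("local transfer entropy averages exactly to the pooled value", {
  set.seed(8)
  sym <- make_symbols_multi(
    replicate(3, mp(rbinom(60, 1, 0.4)), simplify = FALSE),
    replicate(3, mp(rbinom(60, 1, 0.6)), simplify = FALSE),
    c("M", "P")
  )
  for (k in c(1, 3)) {
    lt <- local_transfer_entropy(sym, "leader", "follower", k = k)
    te <- transfer_entropy(sym, "leader", "follower", k = k)
    expect_equal(mean(lt$local_bits), te$te_bits, tolerance = 1e-14)
    expect_equal(attr(lt, "te_bits", exact = TRUE), te$te_bits)
  }
})

test_that("a perfect copy process carries one bit with all-informative steps", {
  src <- mp(rep(c(0, 0, 1, 1), 100))
  dst <- c(src[length(src)], src[-length(src)])
  sym <- make_symbols(src, dst, c("M", "P"))
  te <- transfer_entropy(sym, "leader", "follower", k = 1)
  expect_equal(te$te_bits, 1, tolerance = 0.02)
  lt <- local_transfer_entropy(sym, "leader", "follower", k = 1)
  expect_true(all(lt$local_bits > 0.9))
})

test_that("misinformative transitions yield negative local values", {
  # source usually copies the future, but sometimes anti-copies: at those
  # steps the source lowers the probability of the realized future
  set.seed(9)
  src <- rbinom(400, 1, 0.5)
  dst_next <- ifelse(runif(400) < 0.85, src, 1 - src)
  dst <- c(0, dst_next[-400])
  sym <- make_symbols(mp(src), mp(dst), c("M", "P"))
  lt <- local_transfer_entropy(sym, "leader", "follower", k = 1)
  expect_true(any(lt$local_bits < 0))
  expect_gt(mean(lt$local_bits), 0)
})

test_that("plug-in bias of independent pairs shrinks with series length", {
  set.seed(10)
  mean_te <- vapply(c(100, 1000, 10000), function(n) {
    mean(vapply(1:200, function(r) {
      sym <- make_symbols(mp(rbinom(n, 1, 0.5)), mp(rbinom(n, 1, 0.5)),
                          c("M", "P"))
      transfer_entropy(sym, "leader", "follower", k = 1)$te_bits
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_te) < 0))
  expect_lt(mean_te[3], 0.001)
})

test_that("net transfer entropy is antisymmetric and zero on identical series", {
  set.seed(12)
  sym <- make_symbols_multi(
    replicate(2, mp(rbinom(80, 1, 0.5)), simplify = FALSE),
    replicate(2, mp(rbinom(80, 1, 0.5)), simplify = FALSE),
    c("M", "P")
  )
  net <- net_transfer_entropy(sym, k_lf = 2)
  swapped <- sym
  swapped$role <- ifelse(sym$role == "leader", "follower", "leader")
  attr(swapped, "alphabet") <- attr(sym, "alphabet", exact = TRUE)
  net_swapped <- net_transfer_entropy(swapped, k_lf = 2)
  expect_equal(net$net_bits, -net_swapped$net_bits, tolerance = 1e-14)
  expect_equal(net$te_lf_bits - net$te_fl_bits, net$net_bits)

  x <- mp(rbinom(50, 1, 0.5))
  same <- make_symbols(x, x, c("M", "P"))
  expect_equal(net_transfer_entropy(same, k_lf = 1)$net_bits, 0)
})

test_that("per-trial mode returns one estimate per trial and pools counts", {
  x1 <- mp(rbinom(40, 1, 0.5))
  x2 <- mp(rbinom(40, 1, 0.5))
  y1 <- mp(rbinom(40, 1, 0.5))
  y2 <- mp(rbinom(40, 1, 0.5))
  sym <- make_symbols_multi(list(x1, x2), list(y1, y2), c("M", "P"))
  per <- transfer_entropy(sym, "leader", "follower", k = 1, mode = "per_trial")
  expect_equal(nrow(per$per_trial), 2)
  expect_equal(per$te_bits, mean(per$per_trial$te_bits))

  # each per-trial value equals the pooled estimate of that trial alone
  solo <- transfer_entropy(make_symbols(x1, y1, c("M", "P")),
                           "leader", "follower", k = 1)
  expect_equal(per$per_trial$te_bits[1], solo$te_bits)

  # pooled transition count is additive over trials
  pooled <- transfer_entropy(sym, "leader", "follower", k = 1)
  expect_equal(pooled$n_transitions, sum(per$per_trial$n_transitions))

  # a trial shorter than k+1 is skipped with a warning
  short <- make_symbols_multi(list(x1, mp(c(0, 1))), list(y1, mp(c(1, 0))),
                              c("M", "P"))
  expect_warning(transfer_entropy(short, "leader", "follower", k = 3),
                 "skipped")
})

test_that("normalized transfer entropy is the explained uncertainty fraction", {
  fake <- function(te, h) structure(list(te_bits = te, cond_entropy_bits = h),
                                    class = "tandem_te")
  expect_equal(normalized_te(fake(0.25, 1)), 0.25)
  expect_equal(normalized_te(fake(0.8, 0.8)), 1)
  expect_equal(normalized_te(fake(0, 0.6)), 0)
  expect_equal(normalized_te(fake(0.5, 1), correction = 0.1), 0.4)
  expect_error(normalized_te(fake(0.1, 0)), "self-predictable")
})

test_that("transfer-entropy objects survive a JSON round trip", {
  sym <- make_symbols_multi(
    list(mp(rbinom(30, 1, 0.5)), mp(rbinom(30, 1, 0.5))),
    list(mp(rbinom(30, 1, 0.5)), mp(rbinom(30, 1, 0.5))),
    c("M", "P")
  )
  te <- transfer_entropy(sym, "leader", "follower", k = 2, mode = "per_trial")
  json <- te_to_json(te)
  back <- te_from_json(json)
  expect_equal(back$te_bits, te$te_bits)
  expect_equal(back$k, te$k)
  expect_equal(back$direction, te$direction)
  expect_equal(back$per_trial$te_bits, te$per_trial$te_bits)

  path <- withr::local_tempfile(fileext = ".json")
  te_to_json(te, path)
  expect_equal(te_from_json(paste(readLines(path), collapse = ""))$te_bits,
               te$te_bits)

  # glance/tidy expose the broom-style views
  expect_equal(nrow(glance(te)), 1)
  expect_equal(nrow(tidy(te)), 2)
})
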