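# surrogate-dataset null construction, bias correction, hypothesis tests

# uniform random derangement by rejection; fast for the trial counts (~20)
# used here
sample_derangement <- function(n) {
  if (n < 2) stop_tf("a surrogate pairing needs at least 2 trials")
  repeat {
    perm <- sample.int(n)
    if (!any(perm == seq_len(n))) return(perm)
  }
}

#' Build one surrogate dataset by re-pairing leaders and followers
#'
#' Each leader keeps its own series but is matched with the follower of a
#' different trial (a derangement of trial indices), breaking within-pair
#' causal coupling while preserving every marginal series. The re-paired
#' follower series takes the leader's `trial_id`; if the two series differ
#' in length both are truncated to the shorter.
#'
#' @param x A `tandem_pairs` or `tandem_symbols` tibble with at least 2
#'   trials.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return An object of the same class with followers re-assigned.
#' @export
make_surrogate <- function(x, seed = NULL) {
  stopifnot(inherits(x, "tandem_pairs") || inherits(x, "tandem_symbols"))
  if (!is.null(seed)) set.seed(seed)
  ids <- as.character(sort(unique(x$trial_id)))
  perm <- sample_derangement(length(ids))
  leaders <- dplyr::filter(x, .data$role == "leader")
  followers <- dplyr::filter(x, .data$role == "follower")
  fol_split <- split(followers, followers$trial_id)
  led_split <- split(leaders, leaders$trial_id)
  pieces <- purrr::map(seq_along(ids), function(j) {
    led <- led_split[[ids[j]]]
    fol <- fol_split[[ids[perm[j]]]]
    n <- min(nrow(led), nrow(fol))
    led <- dplyr::slice_head(led, n = n)
    fol <- dplyr::slice_head(fol, n = n)
    fol$trial_id <- ids[j]
    fol$t_index <- led$t_index
    dplyr::bind_rows(led, fol)
  })
  out <- dplyr::bind_rows(pieces)
  out <- restore_meta(tibble::as_tibble(out), x)
  class(out) <- class(x)
  out
}

#' Surrogate ensemble of transfer entropy
#'
#' Repeats the leader/follower re-pairing `n_replicates` times (default 50)
#' and computes the pooled transfer entropy of each surrogate dataset with
#' the same estimator as the experimental value. The ensemble mean is the
#' finite-sample bias correction; per re-paired trial TE values of the
#' first replicate are retained for the rank-sum comparison against
#' per-trial experimental values.
#'
#' @inheritParams transfer_entropy
#' @param n_replicates Number of surrogate datasets.
#' @param seed Integer seed (mandatory: ensembles must be reproducible).
#' @return An object of class `te_surrogates`: per-replicate TE vector,
#'   `mean_bits`, `se_bits` (standard error of the ensemble mean, the
#'   uncertainty on the bias correction), `sd_bits` (ensemble standard
#'   deviation, i.e. the standard error of a single TE estimate under the
#'   re-pairing null -- the scale against which an experimental estimate
#'   is judged), per-pair values of replicate one, and the generating
#'   parameters.
#' @export
surrogate_te <- function(symbols, source = "leader", dest = "follower",
                         k = 1, n_replicates = 50, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  trials <- align_series(symbols, source, dest)
  if (length(trials) < 2) stop_tf("surrogates need at least 2 trials")
  set.seed(seed)
  per_pair <- NULL
  te_reps <- vapply(seq_len(n_replicates), function(r) {
    perm <- sample_derangement(length(trials))
    rep_trials <- repair_trials(trials, perm)
    if (r == 1) {
      vals <- vapply(rep_trials, function(tr) {
        if (length(tr$dest) < k + 1) return(NA_real_)
        plugin_stats(build_transitions(list(tr), k, warn_short = FALSE))$te_bits
      }, numeric(1))
      per_pair <<- tibble::tibble(
        trial_id = vapply(rep_trials, `[[`, character(1), "trial_id"),
        te_bits = vals
      )
    }
    suppressWarnings(
      plugin_stats(build_transitions(rep_trials, k, warn_short = FALSE))$te_bits
    )
  }, numeric(1))
  sd_reps <- if (n_replicates > 1) stats::sd(te_reps) else NA_real_
  structure(
    list(
      per_replicate = te_reps,
      mean_bits = mean(te_reps),
      se_bits = sd_reps / sqrt(n_replicates),
      sd_bits = sd_reps,
      per_pair = per_pair,
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed),
      direction = paste0(source, "->", dest),
      k = as.integer(k),
      period_s = meta(symbols, "period_s") %||% NA_real_,
      pattern = meta(symbols, "pattern") %||% NA_character_
    ),
    class = "te_surrogates"
  )
}

#' Surrogate ensemble of net transfer entropy
#'
#' Both directions are evaluated on the same re-pairings, giving a
#' per-replicate null for the net flow
#' `T[leader->follower] - T[follower->leader]`.
#'
#' @inheritParams net_transfer_entropy
#' @inheritParams surrogate_te
#' @return A list with per-replicate vectors `te_lf`, `te_fl`, `net`, the
#'   ensemble means `mean_lf_bits`, `mean_fl_bits`, `mean_net_bits`,
#'   `se_net_bits` (SE of the ensemble mean) and `sd_net_bits` (ensemble
#'   spread: the null-scale for judging an experimental net TE).
#' @export
surrogate_net_te <- function(symbols, k_lf = 1, k_fl = k_lf,
                             n_replicates = 50, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  lf_trials <- align_series(symbols, "leader", "follower")
  fl_trials <- align_series(symbols, "follower", "leader")
  if (length(lf_trials) < 2) stop_tf("surrogates need at least 2 trials")
  set.seed(seed)
  te_lf <- te_fl <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    perm <- sample_derangement(length(lf_trials))
    te_lf[r] <- suppressWarnings(plugin_stats(
      build_transitions(repair_trials(lf_trials, perm), k_lf, warn_short = FALSE)
    )$te_bits)
    # the same pairing viewed from the other direction: leader of trial
    # perm[j] is the re-paired source for follower j
    inv <- order(perm)
    te_fl[r] <- suppressWarnings(plugin_stats(
      build_transitions(repair_trials(fl_trials, inv), k_fl, warn_short = FALSE)
    )$te_bits)
  }
  net <- te_lf - te_fl
  list(
    te_lf = te_lf, te_fl = te_fl, net = net,
    mean_lf_bits = mean(te_lf), mean_fl_bits = mean(te_fl),
    mean_net_bits = mean(net),
    se_net_bits = if (n_replicates > 1) stats::sd(net) / sqrt(n_replicates) else NA_real_,
    sd_net_bits = if (n_replicates > 1) stats::sd(net) else NA_real_,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  )
}

#' Surrogate-corrected transfer entropy
#'
#' The experimental estimate discounted by the surrogate ensemble mean;
#' may be negative and is reported as-is.
#'
#' @param raw_bits Experimental (pooled) transfer entropy, bits.
#' @param ensemble A `te_surrogates` object, or a number of bits.
#' @return Corrected transfer entropy in bits.
#' @export
corrected_te <- function(raw_bits, ensemble) {
  correction <- if (inherits(ensemble, "te_surrogates")) ensemble$mean_bits
                else as.numeric(ensemble)
  raw_bits - correction
}

#' @method tidy te_surrogates
#' @export
tidy.te_surrogates <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$per_replicate),
                 te_bits = x$per_replicate, direction = x$direction,
                 k = x$k, pattern = x$pattern)
}

#' @method glance te_surrogates
#' @export
glance.te_surrogates <- function(x, ...) {
  tibble::tibble(direction = x$direction, pattern = x$pattern,
                 mean_bits = x$mean_bits, se_bits = x$se_bits,
                 n_replicates = x$n_replicates, k = x$k,
                 period_s = x$period_s, seed = x$seed)
}

#' @export
print.te_surrogates <- function(x, ...) {
  cat(sprintf(
    "<te_surrogates> %d replicates, T[%s] = %.6f +/- %.6f bits (k=%d, seed %d)\n",
    x$n_replicates, x$direction, x$mean_bits, x$se_bits, x$k, x$seed
  ))
  invisible(x)
}

wilcox_row <- function(test, ht, n1, n2 = NA_integer_) {
  tibble::tibble(
    test = test, alternative = "greater",
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n1 = n1, n2 = n2
  )
}

#' One-sided two-sample Wilcoxon rank-sum test (x greater than y)
#'
#' Normal approximation with continuity correction; the statistic W is the
#' Mann-Whitney count of (x, y) pairs with x above y, with maximum
#' `n1 * n2` (400 when both samples have 20 values). Ties take midranks.
#'
#' @param x,y Numeric samples (e.g. per-trial experimental TE vs per-pair
#'   surrogate TE).
#' @return One-row tibble: `test`, `alternative`, `statistic` (W),
#'   `p_value`, `n1`, `n2`.
#' @export
ranksum_greater <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_tf("empty sample")
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "greater", exact = FALSE, correct = TRUE
  ))
  wilcox_row("rank_sum", ht, length(x), length(y))
}

#' One-sided paired Wilcoxon signed-rank test (x greater than y)
#'
#' Normal approximation with continuity correction; V is the sum of ranks
#' of positive differences, with maximum `n(n+1)/2` (210 for 20 pairs) and
#' minimum 0. Zero differences are dropped before ranking.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return One-row tibble: `test`, `alternative`, `statistic` (V),
#'   `p_value`, `n1` (pairs after zero removal).
#' @export
signedrank_greater <- function(x, y) {
  if (length(x) != length(y)) stop_tf("paired samples must have equal length")
  d <- x - y
  if (all(d == 0)) stop_tf("all paired differences are zero")
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, alternative = "greater", exact = FALSE, correct = TRUE
  ))
  wilcox_row("signed_rank", ht, sum(d != 0))
}
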