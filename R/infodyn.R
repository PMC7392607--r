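#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @param tol Tolerance on the total mass.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p, tol = 1e-8) {
  if (any(p < 0)) stop_tf("negative probability mass")
  if (abs(sum(p) - 1) > tol) stop_tf("probabilities do not sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# ---- internal: aligned series and sparse transition tables ----------------

# single-character codes keep k-history keys compact
symbol_code <- c(M = "M", P = "P", CW = "C", CCW = "W")

# split a tandem_symbols tibble into per-trial aligned (src, dest) code
# vectors; src_role = NULL gives destination-only tracks
align_series <- function(symbols, source_role, dest_role) {
  stopifnot(inherits(symbols, "tandem_symbols"))
  dest <- dplyr::filter(symbols, .data$role == dest_role)
  if (nrow(dest) == 0) stop_tf(paste0("no series for role ", dest_role))
  dest <- dplyr::arrange(dest, .data$trial_id, .data$t_index)
  dest_split <- split(dest[c("t_index", "symbol")], dest$trial_id)
  if (is.null(source_role)) {
    return(lapply(names(dest_split), function(id) {
      d <- dest_split[[id]]
      list(trial_id = id, t_index = d$t_index,
           dest = unname(symbol_code[d$symbol]), src = NULL)
    }))
  }
  src <- dplyr::filter(symbols, .data$role == source_role)
  if (nrow(src) == 0) stop_tf(paste0("no series for role ", source_role))
  src <- dplyr::arrange(src, .data$trial_id, .data$t_index)
  src_split <- split(src[c("t_index", "symbol")], src$trial_id)
  ids <- names(dest_split)
  if (!setequal(ids, names(src_split))) {
    stop_tf("source and destination roles cover different trials")
  }
  lapply(ids, function(id) {
    d <- dest_split[[id]]
    s <- src_split[[id]]
    if (length(d$t_index) != length(s$t_index) ||
        !all(d$t_index == s$t_index)) {
      stop_tf(paste0("misaligned source/destination series in trial ", id))
    }
    list(trial_id = id, t_index = d$t_index,
         dest = unname(symbol_code[d$symbol]),
         src = unname(symbol_code[s$symbol]))
  })
}

# re-pair: dest series of trial j with src series of trial perm[j];
# truncated to the shorter of the two
repair_trials <- function(trials, perm) {
  lapply(seq_along(trials), function(j) {
    d <- trials[[j]]
    s <- trials[[perm[j]]]
    n <- min(length(d$dest), length(s$src))
    list(trial_id = d$trial_id, t_index = d$t_index[seq_len(n)],
         dest = d$dest[seq_len(n)], src = s$src[seq_len(n)])
  })
}

# transition records pooled over trials: for each within-trial position i
# (k <= i <= n-1), history = dest[i-k+1..i], future = dest[i+1],
# source-present = src[i]; never crosses a trial boundary
build_transitions <- function(trials, k, warn_short = TRUE) {
  stopifnot(k >= 1)
  recs <- lapply(trials, function(tr) {
    n <- length(tr$dest)
    if (n < k + 1) {
      if (warn_short) {
        warning(sprintf("trial %s has %d symbols, fewer than k+1 = %d; skipped",
                        tr$trial_id, n, k + 1), call. = FALSE)
      }
      return(NULL)
    }
    if (n > 1 && !all(diff(tr$t_index) == 1L)) {
      stop_tf(paste0("non-contiguous symbol indices in trial ", tr$trial_id))
    }
    idx <- k:(n - 1)
    collapsed <- paste(tr$dest, collapse = "")
    list(
      trial_id = rep(tr$trial_id, length(idx)),
      t_index = tr$t_index[idx + 1],
      hist = substring(collapsed, idx - k + 1, idx),
      fut = tr$dest[idx + 1],
      src = if (is.null(tr$src)) NULL else tr$src[idx]
    )
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) stop_tf("no trial long enough for the requested history length")
  list(
    trial_id = unlist(lapply(recs, `[[`, "trial_id"), use.names = FALSE),
    t_index = unlist(lapply(recs, `[[`, "t_index"), use.names = FALSE),
    hist = unlist(lapply(recs, `[[`, "hist"), use.names = FALSE),
    fut = unlist(lapply(recs, `[[`, "fut"), use.names = FALSE),
    src = if (is.null(recs[[1]]$src)) NULL
          else unlist(lapply(recs, `[[`, "src"), use.names = FALSE)
  )
}

# plug-in estimates from pooled transitions; probabilities are empirical
# block frequencies, only observed blocks are ever stored or visited.
# Returns per-transition local TE so mean(local) is exactly pooled TE.
plugin_stats <- function(tr) {
  h <- tr$hist
  hf <- paste0(tr$hist, "\1", tr$fut)
  c_h <- count_per_element(h)
  c_hf <- count_per_element(hf)
  cond_h <- mean(-log2(c_hf / c_h))
  if (is.null(tr$src)) {
    return(list(cond_entropy_bits = cond_h, n = length(h)))
  }
  hs <- paste0(tr$hist, "\1", tr$src)
  hfs <- paste0(hf, "\1", tr$src)
  c_hs <- count_per_element(hs)
  c_hfs <- count_per_element(hfs)
  local <- log2((c_hfs / c_hs) / (c_hf / c_h))
  cond_h_src <- mean(-log2(c_hfs / c_hs))
  list(
    local = local,
    te_bits = mean(local),
    cond_entropy_bits = cond_h,
    cond_entropy_src_bits = cond_h_src,
    n = length(h)
  )
}

new_tandem_te <- function(source, dest, stats, k, symbols, mode,
                          per_trial = NULL) {
  structure(
    list(
      direction = paste0(source, "->", dest),
      source = source, dest = dest,
      te_bits = stats$te_bits,
      cond_entropy_bits = stats$cond_entropy_bits,
      k = as.integer(k),
      period_s = meta(symbols, "period_s") %||% NA_real_,
      pattern = meta(symbols, "pattern") %||% NA_character_,
      mode = mode,
      n_transitions = stats$n,
      per_trial = per_trial
    ),
    class = "tandem_te"
  )
}

#' Conditional entropy of a role's future given its own k-history
#'
#' Plug-in estimate of H(X[i+1] | X[i-k+1..i]) in bits, pooled over all
#' trials of the series (block frequencies are counted within trials and
#' summed over them).
#'
#' @param symbols A `tandem_symbols` tibble.
#' @param role Which role's series to use.
#' @param k History length (number of past symbols conditioned on).
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(symbols, role = "follower", k = 1) {
  trials <- align_series(symbols, NULL, role)
  plugin_stats(build_transitions(trials, k))$cond_entropy_bits
}

#' Transfer entropy between leader and follower symbol series
#'
#' The reduction in uncertainty about the destination's next symbol given
#' the source's present symbol, beyond what the destination's own k-history
#' already provides:
#' \deqn{T_{S \to D} = \sum p(d_{i+1}, d_i^{(k)}, s_i)
#'   \log_2 \frac{p(d_{i+1} \mid d_i^{(k)}, s_i)}
#'               {p(d_{i+1} \mid d_i^{(k)})}.}
#' Probabilities are plug-in block frequencies; only observed blocks are
#' counted (sparse), so history lengths up to 20 are practical on binary or
#' ternary alphabets. In `"pooled"` mode (the headline estimate)
#' frequencies are pooled over all trials; in `"per_trial"` mode one
#' estimate is computed per trial from that trial's counts alone and the
#' headline value is their mean (per-trial values feed the Wilcoxon tests).
#'
#' @param symbols A `tandem_symbols` tibble containing both roles.
#' @param source,dest Source and destination roles (direction is
#'   source to destination).
#' @param k Destination history length; the source enters only through its
#'   present symbol.
#' @param mode `"pooled"` or `"per_trial"`.
#' @return A `tandem_te` object; see [tidy.tandem_te()] and
#'   [glance.tandem_te()].
#' @export
transfer_entropy <- function(symbols, source = "leader", dest = "follower",
                             k = 1, mode = c("pooled", "per_trial")) {
  mode <- match.arg(mode)
  trials <- align_series(symbols, source, dest)
  if (mode == "pooled") {
    stats <- plugin_stats(build_transitions(trials, k))
    return(new_tandem_te(source, dest, stats, k, symbols, mode))
  }
  rows <- purrr::map(trials, function(tr) {
    if (length(tr$dest) < k + 1) {
      warning(sprintf("trial %s has %d symbols, fewer than k+1 = %d; skipped",
                      tr$trial_id, length(tr$dest), k + 1), call. = FALSE)
      return(NULL)
    }
    s <- plugin_stats(build_transitions(list(tr), k, warn_short = FALSE))
    tibble::tibble(trial_id = tr$trial_id, te_bits = s$te_bits,
                   cond_entropy_bits = s$cond_entropy_bits,
                   n_transitions = s$n)
  })
  per_trial <- dplyr::bind_rows(rows)
  if (nrow(per_trial) == 0) stop_tf("no trial long enough for the requested history length")
  stats <- list(
    te_bits = mean(per_trial$te_bits),
    cond_entropy_bits = mean(per_trial$cond_entropy_bits),
    n = sum(per_trial$n_transitions)
  )
  new_tandem_te(source, dest, stats, k, symbols, mode, per_trial = per_trial)
}

#' Local transfer entropy series
#'
#' The per-time-step log-ratio whose average is pooled transfer entropy:
#' positive values mark transitions where the source was informative about
#' the realized future, negative values mark misinformative ones.
#' Probabilities are the pooled plug-in estimates, so
#' `mean(local_bits)` equals the pooled TE exactly.
#'
#' @inheritParams transfer_entropy
#' @return A tibble of class `local_te` with columns `trial_id`, `t_index`
#'   (destination time index of the predicted symbol), `local_bits`;
#'   attributes carry `te_bits`, `k`, `direction`, `period_s`, `pattern`.
#' @export
local_transfer_entropy <- function(symbols, source = "leader",
                                   dest = "follower", k = 1) {
  trials <- align_series(symbols, source, dest)
  tr <- build_transitions(trials, k)
  stats <- plugin_stats(tr)
  out <- tibble::tibble(
    trial_id = tr$trial_id, t_index = tr$t_index, local_bits = stats$local
  )
  structure(
    out,
    te_bits = stats$te_bits,
    k = as.integer(k),
    direction = paste0(source, "->", dest),
    period_s = meta(symbols, "period_s") %||% NA_real_,
    pattern = meta(symbols, "pattern") %||% NA_character_,
    class = c("local_te", class(tibble::tibble()))
  )
}

#' Net transfer entropy (direction of predominant information flow)
#'
#' `T[leader -> follower] - T[follower -> leader]`; positive when
#' information flows predominantly from leader to follower, negative when
#' the follower is the predominant source. Swapping the roles flips the
#' sign exactly.
#'
#' @inheritParams transfer_entropy
#' @param k_lf,k_fl History lengths for the leader-to-follower and
#'   follower-to-leader estimates (usually equal).
#' @return One-row tibble with `te_lf_bits`, `te_fl_bits`, `net_bits`,
#'   `k_lf`, `k_fl`, `period_s`, `pattern`.
#' @export
net_transfer_entropy <- function(symbols, k_lf = 1, k_fl = k_lf,
                                 mode = c("pooled", "per_trial")) {
  mode <- match.arg(mode)
  lf <- transfer_entropy(symbols, "leader", "follower", k = k_lf, mode = mode)
  fl <- transfer_entropy(symbols, "follower", "leader", k = k_fl, mode = mode)
  tibble::tibble(
    te_lf_bits = lf$te_bits, te_fl_bits = fl$te_bits,
    net_bits = lf$te_bits - fl$te_bits,
    k_lf = as.integer(k_lf), k_fl = as.integer(k_fl),
    period_s = lf$period_s, pattern = lf$pattern
  )
}

#' Normalized transfer entropy
#'
#' Transfer entropy (optionally discounted by a surrogate-derived
#' correction) divided by the destination's conditional entropy
#' H(D[i+1] | D^(k)): the fraction of the destination's remaining
#' uncertainty explained by the source, clamped to `[0, 1]`.
#'
#' @param te A `tandem_te` object.
#' @param correction Bits subtracted from the raw estimate before
#'   normalizing (default 0, i.e. raw; pass a surrogate ensemble mean for
#'   the bias-corrected version).
#' @return A fraction in `[0, 1]`.
#' @export
normalized_te <- function(te, correction = 0) {
  stopifnot(inherits(te, "tandem_te"))
  if (te$cond_entropy_bits <= 0) {
    stop_tf("conditional entropy is zero: destination is fully self-predictable")
  }
  min(1, max(0, (te$te_bits - correction) / te$cond_entropy_bits))
}

# ---- broom-style methods and serialization --------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transfer-entropy estimate
#'
#' For `per_trial` mode, one row per trial; for pooled mode the single
#' pooled row.
#'
#' @param x A `tandem_te` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tandem_te
#' @export
tidy.tandem_te <- function(x, ...) {
  if (!is.null(x$per_trial)) {
    dplyr::mutate(x$per_trial, direction = x$direction, k = x$k,
                  period_s = x$period_s, pattern = x$pattern)
  } else {
    glance.tandem_te(x)
  }
}

#' One-row summary of a transfer-entropy estimate
#'
#' @inheritParams tidy.tandem_te
#' @return A one-row tibble.
#' @method glance tandem_te
#' @export
glance.tandem_te <- function(x, ...) {
  tibble::tibble(
    direction = x$direction, pattern = x$pattern, te_bits = x$te_bits,
    cond_entropy_bits = x$cond_entropy_bits, k = x$k,
    period_s = x$period_s, mode = x$mode, n_transitions = x$n_transitions
  )
}

#' @export
print.tandem_te <- function(x, ...) {
  cat(sprintf(
    "<tandem_te> T[%s] = %.6f bits (H(dest future | k=%d history) = %.6f bits)\n",
    x$direction, x$te_bits, x$k, x$cond_entropy_bits
  ))
  cat(sprintf("  pattern %s, period %.4f s, mode %s, %d transitions\n",
              x$pattern, x$period_s, x$mode, x$n_transitions))
  invisible(x)
}

#' Serialize / restore a transfer-entropy estimate as JSON
#'
#' Field names are stable; numeric fields round-trip at full precision.
#'
#' @param te A `tandem_te` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `te_to_json()`: the JSON string (invisibly when written to
#'   file); `te_from_json()`: the restored `tandem_te`.
#' @export
te_to_json <- function(te, path = NULL) {
  stopifnot(inherits(te, "tandem_te"))
  payload <- unclass(te)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname te_to_json
#' @param json JSON string or path to a JSON file.
#' @export
te_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  if (!is.null(payload$per_trial)) {
    payload$per_trial <- tibble::as_tibble(payload$per_trial)
  }
  payload$k <- as.integer(payload$k)
  structure(payload, class = "tandem_te")
}
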