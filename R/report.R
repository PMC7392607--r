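# assemble the study-style summary tables for a dataset

#' Full information-flow report for a trajectory dataset
#'
#' Runs the complete analysis for each requested (pattern, sampling
#' period, history length) configuration and assembles three summary
#' tables mirroring the standard presentation of tandem-run information
#' flow:
#'
#' * `configurations`: species, number of tandem runs, pattern, sampling
#'   period, number of time steps per series, history length;
#' * `te_stats`: per-direction experimental transfer entropy (mean and
#'   standard error over per-trial estimates), surrogate TE (mean and SE
#'   over replicates), surrogate-corrected pooled TE, and normalized TE of
#'   the predominant direction (per-trial TE over per-trial conditional
#'   entropy, mean and SE);
#' * `tests`: one-sided Wilcoxon rank-sum tests of experimental per-trial
#'   TE against per-pair surrogate TE in each direction, and one-sided
#'   paired signed-rank tests between the two directions.
#'
#' @param data A `tandem_pairs` tibble at its native sampling period.
#' @param configs Data frame with columns `pattern`, `period_s`, `k` (one
#'   row per configuration to analyse).
#' @param n_surrogates Surrogate replicates per direction (default 50).
#' @param seed Integer seed controlling all surrogate pairings.
#' @param q Pause-threshold percentile.
#' @return A list of class `te_report` with elements `configurations`,
#'   `te_stats`, `tests`.
#' @export
te_report <- function(data, configs, n_surrogates = 50, seed, q = 10) {
  stopifnot(inherits(data, "tandem_pairs"),
            all(c("pattern", "period_s", "k") %in% names(configs)))
  species <- meta(data, "species")
  n_runs <- dplyr::n_distinct(data$trial_id)
  se <- function(x) stats::sd(x) / sqrt(length(x))

  rows <- purrr::map(seq_len(nrow(configs)), function(i) {
    pattern <- configs$pattern[i]
    period <- configs$period_s[i]
    k <- configs$k[i]
    sub <- subsample_trajectories(data, period)
    symbols <- encode_pattern(sub, pattern, q = q)
    n_steps <- min(dplyr::count(sub, .data$trial_id, .data$role)$n)

    lf_pool <- transfer_entropy(symbols, "leader", "follower", k = k)
    fl_pool <- transfer_entropy(symbols, "follower", "leader", k = k)
    lf_trial <- transfer_entropy(symbols, "leader", "follower", k = k,
                                 mode = "per_trial")
    fl_trial <- transfer_entropy(symbols, "follower", "leader", k = k,
                                 mode = "per_trial")
    surr_lf <- surrogate_te(symbols, "leader", "follower", k = k,
                            n_replicates = n_surrogates,
                            seed = seed + 1000L * i)
    surr_fl <- surrogate_te(symbols, "follower", "leader", k = k,
                            n_replicates = n_surrogates,
                            seed = seed + 1000L * i + 500L)

    net <- lf_pool$te_bits - fl_pool$te_bits
    dominant <- if (net >= 0) "leader->follower" else "follower->leader"
    dom_trial <- if (net >= 0) lf_trial else fl_trial
    norm_trial <- dom_trial$per_trial$te_bits /
      dom_trial$per_trial$cond_entropy_bits

    list(
      config = tibble::tibble(
        species = species, n_tandem_runs = n_runs, pattern = pattern,
        period_s = period, n_time_steps = n_steps, k = as.integer(k)
      ),
      stats = tibble::tibble(
        species = species, pattern = pattern,
        te_lf_bits = mean(lf_trial$per_trial$te_bits),
        te_lf_se = se(lf_trial$per_trial$te_bits),
        te_lf_surr_bits = surr_lf$mean_bits,
        te_lf_surr_se = surr_lf$se_bits,
        te_fl_bits = mean(fl_trial$per_trial$te_bits),
        te_fl_se = se(fl_trial$per_trial$te_bits),
        te_fl_surr_bits = surr_fl$mean_bits,
        te_fl_surr_se = surr_fl$se_bits,
        pooled_te_lf_bits = lf_pool$te_bits,
        pooled_te_fl_bits = fl_pool$te_bits,
        corrected_te_lf_bits = corrected_te(lf_pool$te_bits, surr_lf),
        corrected_te_fl_bits = corrected_te(fl_pool$te_bits, surr_fl),
        net_bits = net,
        dominant_direction = dominant,
        norm_te_bits = mean(norm_trial),
        norm_te_se = se(norm_trial)
      ),
      tests = dplyr::bind_rows(
        dplyr::mutate(
          ranksum_greater(lf_trial$per_trial$te_bits,
                          stats::na.omit(surr_lf$per_pair$te_bits)),
          hypothesis = "T[L->F] > T[L->F] surrogate", .before = 1
        ),
        dplyr::mutate(
          ranksum_greater(fl_trial$per_trial$te_bits,
                          stats::na.omit(surr_fl$per_pair$te_bits)),
          hypothesis = "T[F->L] > T[F->L] surrogate", .before = 1
        ),
        dplyr::mutate(
          signedrank_greater(lf_trial$per_trial$te_bits,
                             fl_trial$per_trial$te_bits),
          hypothesis = "T[L->F] > T[F->L]", .before = 1
        ),
        dplyr::mutate(
          signedrank_greater(fl_trial$per_trial$te_bits,
                             lf_trial$per_trial$te_bits),
          hypothesis = "T[F->L] > T[L->F]", .before = 1
        )
      ) |>
        dplyr::mutate(species = species, pattern = pattern, .before = 1)
    )
  })

  structure(
    list(
      configurations = dplyr::bind_rows(purrr::map(rows, "config")),
      te_stats = dplyr::bind_rows(purrr::map(rows, "stats")),
      tests = dplyr::bind_rows(purrr::map(rows, "tests")),
      seed = as.integer(seed), n_surrogates = as.integer(n_surrogates), q = q
    ),
    class = "te_report"
  )
}

#' Write a report's tables to delimited text and JSON
#'
#' @param report A `te_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_te_report <- function(report, dir) {
  stopifnot(inherits(report, "te_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$configurations,
                   file.path(dir, "configurations.csv"), progress = FALSE)
  readr::write_csv(report$te_stats, file.path(dir, "te_stats.csv"),
                   progress = FALSE)
  readr::write_csv(report$tests, file.path(dir, "tests.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    report[c("configurations", "te_stats", "tests", "seed",
             "n_surrogates", "q")],
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.te_report <- function(x, ...) {
  cat("<te_report>\n-- configurations --\n")
  print(x$configurations)
  cat("-- transfer entropy --\n")
  print(x$te_stats)
  cat("-- hypothesis tests --\n")
  print(x$tests)
  invisible(x)
}
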