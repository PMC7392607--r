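# Independent dense-enumeration oracle for the plug-in information
# quantities. Deliberately naive: it enumerates the full alphabet^k x
# alphabet x alphabet block space and counts occurrences with explicit
# vector scans, sharing no code with the package's sparse estimator.

oracle_transitions <- function(dest_trials, src_trials, k) {
  hists <- futs <- srcs <- character(0)
  for (t in seq_along(dest_trials)) {
    d <- as.character(dest_trials[[t]])
    s <- as.character(src_trials[[t]])
    n <- length(d)
    if (n < k + 1) next
    for (i in k:(n - 1)) {
      hists <- c(hists, paste(d[(i - k + 1):i], collapse = "|"))
      futs <- c(futs, d[i + 1])
      srcs <- c(srcs, s[i])
    }
  }
  list(hists = hists, futs = futs, srcs = srcs)
}

oracle_hist_space <- function(alphabet, k) {
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k), stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "|")
}

# transfer entropy by direct summation of the defining formula over the
# dense block space
oracle_te <- function(src_trials, dest_trials, k, alphabet) {
  tr <- oracle_transitions(dest_trials, src_trials, k)
  N <- length(tr$futs)
  te <- 0
  for (h in oracle_hist_space(alphabet, k)) {
    for (f in alphabet) {
      for (s in alphabet) {
        c_hfs <- sum(tr$hists == h & tr$futs == f & tr$srcs == s)
        if (c_hfs == 0) next
        c_hs <- sum(tr$hists == h & tr$srcs == s)
        c_hf <- sum(tr$hists == h & tr$futs == f)
        c_h <- sum(tr$hists == h)
        te <- te + (c_hfs / N) * log2((c_hfs / c_hs) / (c_hf / c_h))
      }
    }
  }
  te
}

# H(future | k-history) by direct summation
oracle_cond_entropy <- function(dest_trials, k, alphabet) {
  tr <- oracle_transitions(dest_trials, dest_trials, k)
  N <- length(tr$futs)
  h_out <- 0
  for (h in oracle_hist_space(alphabet, k)) {
    for (f in alphabet) {
      c_hf <- sum(tr$hists == h & tr$futs == f)
      if (c_hf == 0) next
      c_h <- sum(tr$hists == h)
      h_out <- h_out - (c_hf / N) * log2(c_hf / c_h)
    }
  }
  h_out
}

# H(future | k-history, source-present) by direct summation
oracle_cond_entropy_src <- function(src_trials, dest_trials, k, alphabet) {
  tr <- oracle_transitions(dest_trials, src_trials, k)
  N <- length(tr$futs)
  h_out <- 0
  for (h in oracle_hist_space(alphabet, k)) {
    for (f in alphabet) {
      for (s in alphabet) {
        c_hfs <- sum(tr$hists == h & tr$futs == f & tr$srcs == s)
        if (c_hfs == 0) next
        c_hs <- sum(tr$hists == h & tr$srcs == s)
        h_out <- h_out - (c_hfs / N) * log2(c_hfs / c_hs)
      }
    }
  }
  h_out
}
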