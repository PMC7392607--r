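# internal helpers shared across modules

# per-element group counts for a character key vector, O(n) via hashing
count_per_element <- function(keys) {
  first <- match(keys, keys)
  tabulate(first, nbins = length(keys))[first]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

tandem_attr_names <- c(
  "frame_rate", "period_s", "species", "body_length_mm", "y_down"
)

# copy trajectory/symbol metadata attributes from `from` onto `to`
restore_meta <- function(to, from, extra = list()) {
  for (a in tandem_attr_names) {
    if (!is.null(attr(from, a, exact = TRUE))) {
      attr(to, a) <- attr(from, a, exact = TRUE)
    }
  }
  for (a in names(extra)) attr(to, a) <- extra[[a]]
  to
}

meta <- function(x, name) attr(x, name, exact = TRUE)

stop_structural <- function(msg) {
  rlang::abort(msg, class = c("tandemflow_structural_error", "tandemflow_error"))
}

stop_parse <- function(msg) {
  rlang::abort(msg, class = c("tandemflow_parse_error", "tandemflow_error"))
}

stop_tf <- function(msg) {
  rlang::abort(msg, class = "tandemflow_error")
}

# near-equality for sampling periods given printed (4-decimal) precision
same_period <- function(a, b, tol = 5e-4) {
  is.finite(a) && is.finite(b) && abs(a - b) <= tol
}
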