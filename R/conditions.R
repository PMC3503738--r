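# Classed error conditions so callers (and tests) can distinguish failure modes.

calfpkpd_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "calfpkpd_error")))
}

abort_invalid_parameter <- function(msg) calfpkpd_abort(msg, "calfpkpd_invalid_parameter")
abort_insufficient_data <- function(msg) calfpkpd_abort(msg, "calfpkpd_insufficient_data")
abort_stripping_failure <- function(msg) calfpkpd_abort(msg, "calfpkpd_stripping_failure")
abort_selection_error   <- function(msg) calfpkpd_abort(msg, "calfpkpd_selection_error")
abort_parse_error       <- function(msg) calfpkpd_abort(msg, "calfpkpd_parse_error")
abort_internal          <- function(msg) calfpkpd_abort(msg, "calfpkpd_internal_error")

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_invalid_parameter(sprintf("`%s` must be a single positive finite number", what))
  }
  invisible(x)
}
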