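# Classed conditions so callers (and tests) can distinguish failure modes.

rm_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("ramanmark_error_", class),
                                          "ramanmark_error")))
}

rm_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("ramanmark_warning_", class),
                                          "ramanmark_warning")))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    rm_abort(sprintf("%s contains non-finite values", what), "nonfinite")
  }
  invisible(x)
}
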