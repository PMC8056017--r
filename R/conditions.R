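# Classed error conditions so callers can distinguish contract violations
# (e.g. too few assessments) from numerical failures.

stop_d50 <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "d50als_error"), call = call))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
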