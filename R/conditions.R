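# Classed conditions so the pipeline can map failures to reason codes.

mn_error <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "metanova_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

mn_warn <- function(class, message) {
  warning(warningCondition(message, class = c(class, "metanova_warning")))
}
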