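## Classed error conditions so callers (and tests) can distinguish failure
## modes without string-matching messages. Every carcrac error carries the
## class "carcrac_error" plus one specific subclass.

carcrac_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(class, "carcrac_error"),
    call = call
  ))
}

carcrac_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "carcrac_warning")))
}
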