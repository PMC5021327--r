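# Classed conditions so callers (and the CLI) can distinguish bad input from
# numerical failure.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mutet_validation_error", "mutet_error")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mutet_numeric_error", "mutet_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
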