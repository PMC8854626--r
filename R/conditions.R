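# Classed error conditions so callers/tests can discriminate failure modes.

col4gly_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "col4gly_error")))
}

col4gly_warning <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "col4gly_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
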