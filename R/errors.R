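# Structured condition helpers. Every featherkit error carries a specific
# class (e.g. "CanvasOverflow") plus "featherkit_error", so callers can
# dispatch with tryCatch(..., CanvasOverflow = ...).

fk_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "featherkit_error")))
}

fk_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) fk_stop(class, msg, ...)
  invisible(TRUE)
}
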