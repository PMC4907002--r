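## Structured error conditions. Every domain error signalled by the package
## carries a specific condition class (e.g. "MultiReferenceRegion") in front of
## "faldorError", so callers can dispatch on the failure mode rather than match
## message text.

faldorError <- function(class, message, ...) {
  structure(
    class = c(class, "faldorError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stopFaldor <- function(class, message, ...) {
  stop(faldorError(class, message, ...))
}

faldorWarning <- function(class, message, ...) {
  structure(
    class = c(class, "faldorWarning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}
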