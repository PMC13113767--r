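# Classed conditions so callers can distinguish failure modes.

ckicsError <- function(class, message, call = sys.call(-1), ...) {
  structure(
    class = c(class, "ckicsError", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

packingError <- function(message, ...) {
  stop(ckicsError("PackingError", message, ...))
}

fitError <- function(message, ...) {
  stop(ckicsError("FitError", message, ...))
}

windowError <- function(message, ...) {
  stop(ckicsError("WindowError", message, ...))
}

configError <- function(message, ...) {
  stop(ckicsError("ConfigError", message, ...))
}

ioError <- function(message, ...) {
  stop(ckicsError("IOError", message, ...))
}
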