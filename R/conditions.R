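# Classed error conditions so callers (and the CLI) can categorize failures.

ssv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ssv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_param  <- function(msg, ...) ssv_stop("ssv_param_error",  msg, ...)
abort_io     <- function(msg, ...) ssv_stop("ssv_io_error",     msg, ...)
abort_format <- function(msg, ...) ssv_stop("ssv_format_error", msg, ...)
abort_data   <- function(msg, ...) ssv_stop("ssv_data_error",   msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
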