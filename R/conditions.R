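# Typed conditions: every user-facing failure carries a machine-readable
# class so the evaluation harness can record model failures without aborting.

abort_rmicast <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "rmicast_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @keywords internal
warn_rmicast <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "rmicast_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}
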