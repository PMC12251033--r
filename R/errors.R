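#' @keywords internal
gc_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("gaitcue_error_", class),
                                     "gaitcue_error", "error", "condition"),
                      call = call))
}

gc_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) gc_abort(msg, class, call = sys.call(-1))
  invisible(TRUE)
}
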