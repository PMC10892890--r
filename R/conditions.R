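# Classed conditions so callers can distinguish bad inputs from numerical
# failures. All inherit from "insula_error".

insula_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "insula_error", "error"),
                      call = call))
}

abort_validation  <- function(msg) insula_abort(msg, "insula_validation_error")
abort_format      <- function(msg) insula_abort(msg, "insula_format_error")
abort_degenerate  <- function(msg) insula_abort(msg, "insula_degenerate_error")
abort_coverage    <- function(msg) insula_abort(msg, "insula_coverage_error")
abort_domain      <- function(msg) insula_abort(msg, "insula_domain_error")

abort_convergence <- function(msg, trace = NULL) {
  stop(errorCondition(msg,
                      class = c("insula_convergence_error", "insula_error",
                                "error"),
                      trace = trace))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
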