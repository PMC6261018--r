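# Classed conditions so callers can distinguish recoverable failures
# (e.g. a too-small reference class, which ARC handles by dropping the
# bootstrap replicate) from genuine misuse.

stop_invalid_input <- function(msg) {
  rlang::abort(msg, class = "arclfdr_invalid_input")
}

stop_fit_failure <- function(msg) {
  rlang::abort(msg, class = "arclfdr_fit_failure")
}

stop_refclass_too_small <- function(msg) {
  rlang::abort(msg, class = "arclfdr_refclass_too_small")
}

stop_procedure_failure <- function(msg) {
  rlang::abort(msg, class = "arclfdr_procedure_failure")
}

stop_resampling_failure <- function(msg) {
  rlang::abort(msg, class = "arclfdr_resampling_failure")
}
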