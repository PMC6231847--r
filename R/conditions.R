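# Classed conditions so callers (and the command-line shim) can map failures
# to meaningful exit codes: config -> 2, data/schema -> 3, insufficient -> 4.

abort_config <- function(message, ...) {
  rlang::abort(message, class = "dqspc_config_error", ...)
}

abort_schema <- function(message, ...) {
  rlang::abort(message, class = "dqspc_schema_error", ...)
}

abort_insufficient <- function(message, ...) {
  rlang::abort(message, class = "dqspc_insufficient_data_error", ...)
}
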