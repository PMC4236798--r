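# Structured conditions so callers (and the CLI) can map failure kinds to
# exit codes: config errors -> 2, data/model errors -> 3.

stop_config <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("hedri_config_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_data <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("hedri_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_degenerate <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("hedri_degenerate_error", "hedri_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_separation <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("hedri_separation_error", "hedri_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}
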