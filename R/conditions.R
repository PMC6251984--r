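# Structured conditions so callers (and the CLI) can distinguish bad input
# from internal failures.

err_input <- function(fmt, ...) {
  stop(structure(
    class = c("gtv_input_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

err_usage <- function(fmt, ...) {
  stop(structure(
    class = c("gtv_usage_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}
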