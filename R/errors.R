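# Classed error conditions so callers can distinguish failure modes.
# All inherit from "memprobe_error".

abort_memprobe <- function(message, class) {
  stop(errorCondition(message, class = c(class, "memprobe_error")))
}

abort_input <- function(message) abort_memprobe(message, "memprobe_input_error")
abort_degenerate <- function(message) abort_memprobe(message, "memprobe_degenerate_signal_error")
abort_no_transition <- function(message) abort_memprobe(message, "memprobe_no_transition_error")
abort_schema <- function(message) abort_memprobe(message, "memprobe_schema_error")
abort_composition <- function(message) abort_memprobe(message, "memprobe_composition_error")
abort_missing_data <- function(message) abort_memprobe(message, "memprobe_missing_data_error")

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    abort_input(sprintf("`%s` must be finite numeric (got %s)", name,
                        paste(utils::head(format(x), 3), collapse = ", ")))
  }
  invisible(x)
}

check_scalar <- function(x, name) {
  check_finite(x, name)
  if (length(x) != 1) abort_input(sprintf("`%s` must be a single number", name))
  invisible(x)
}
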