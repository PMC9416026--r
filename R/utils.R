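# Classed conditions so callers (and the CLI) can map failure kinds to
# exit codes without string matching.
stop_hsigan <- function(msg, class) {
  stop(structure(class = c(class, "hsigan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_config <- function(msg) stop_hsigan(msg, "hsigan_config_error")
stop_data <- function(msg) stop_hsigan(msg, "hsigan_data_error")
stop_format <- function(msg) stop_hsigan(msg, "hsigan_format_error")
stop_dimension <- function(msg) stop_hsigan(msg, "hsigan_dimension_error")
stop_numeric <- function(msg) stop_hsigan(msg, "hsigan_numeric_error")
stop_usage <- function(msg) stop_hsigan(msg, "hsigan_usage_error")
stop_range <- function(msg) stop_hsigan(msg, "hsigan_range_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == as.integer(x)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
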