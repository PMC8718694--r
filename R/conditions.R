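## Condition helpers: every recoverable failure mode raised by the package gets
## a dedicated condition class so callers (and the pipeline driver) can react
## to the kind of failure rather than matching message text.

wcflux_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "wcflux_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_invalid_argument <- function(message) {
  wcflux_error("wcflux_invalid_argument", message, call = sys.call(-1))
}

stop_degenerate_input <- function(message) {
  wcflux_error("wcflux_degenerate_input", message, call = sys.call(-1))
}

stop_key_not_found <- function(message) {
  wcflux_error("wcflux_key_not_found", message, call = sys.call(-1))
}

stop_insufficient_reference <- function(message) {
  wcflux_error("wcflux_insufficient_reference", message, call = sys.call(-1))
}

stop_degenerate_labels <- function(message) {
  wcflux_error("wcflux_degenerate_labels", message, call = sys.call(-1))
}

stop_missing_series <- function(message) {
  wcflux_error("wcflux_missing_series", message, call = sys.call(-1))
}

stop_undefined_statistic <- function(message) {
  wcflux_error("wcflux_undefined_statistic", message, call = sys.call(-1))
}

stop_unclassified_phenotype <- function(message) {
  wcflux_error("wcflux_unclassified_phenotype", message, call = sys.call(-1))
}

stop_parse_error <- function(message) {
  wcflux_error("wcflux_parse_error", message, call = sys.call(-1))
}

## Label constants used throughout: a flux is "normal" when it stays within
## the wild-type behavioural range, "abnormal" otherwise.
LABEL_NORMAL <- "normal"
LABEL_ABNORMAL <- "abnormal"

`%||%` <- function(a, b) if (is.null(a)) b else a
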