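# Structured error conditions so callers (and tests) can discriminate failure
# modes without matching message text.

stop_paleodem <- function(class, message, call. = FALSE, ...) {
  cnd <- structure(
    class = c(paste0("paleodem_", class), "paleodem_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  )
  stop(cnd)
}

# shorthands used across modules
stop_format     <- function(msg, ...) stop_paleodem("format_error", msg, ...)
stop_value      <- function(msg, ...) stop_paleodem("value_error", msg, ...)
stop_range      <- function(msg, ...) stop_paleodem("range_error", msg, ...)
stop_coverage   <- function(msg, ...) stop_paleodem("coverage_error", msg, ...)
stop_config     <- function(msg, ...) stop_paleodem("config_error", msg, ...)
stop_schema     <- function(msg, ...) stop_paleodem("schema_error", msg, ...)
stop_alignment  <- function(msg, ...) stop_paleodem("alignment_error", msg, ...)
stop_empty      <- function(msg, ...) stop_paleodem("empty_error", msg, ...)
stop_model      <- function(msg, ...) stop_paleodem("model_error", msg, ...)
stop_spec       <- function(msg, ...) stop_paleodem("spec_error", msg, ...)
stop_dependency <- function(msg, ...) stop_paleodem("dependency_error", msg, ...)
stop_validation <- function(msg, ...) stop_paleodem("validation_error", msg, ...)
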