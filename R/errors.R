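# Classed conditions so callers (and tests) can distinguish failure modes.
# All classes carry the "txr_error" (or "txr_warning") parent.

txr_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "txr_error"), ...)
}

txr_warn <- function(class, message, ...) {
  rlang::warn(message, class = c(class, "txr_warning"), ...)
}

abort_duplicate_id <- function(message, ...) {
  txr_abort("txr_duplicate_id_error", message, ...)
}

abort_parse <- function(message, ...) {
  txr_abort("txr_parse_error", message, ...)
}

abort_missing_value <- function(message, ...) {
  txr_abort("txr_missing_value_error", message, ...)
}

abort_design <- function(message, ...) {
  txr_abort("txr_design_error", message, ...)
}

abort_config <- function(message, ...) {
  txr_abort("txr_config_error", message, ...)
}

abort_value <- function(message, ...) {
  txr_abort("txr_value_error", message, ...)
}
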