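# Classed conditions so callers/tests can distinguish failure modes.

scbc_abort <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "scbc_error"), call = call))
}

stop_format     <- function(msg) scbc_abort("scbc_format_error", msg)
stop_integrity  <- function(msg) scbc_abort("scbc_integrity_error", msg)
stop_domain     <- function(msg) scbc_abort("scbc_domain_error", msg)
stop_config     <- function(msg) scbc_abort("scbc_config_error", msg)
stop_sample_size <- function(msg) scbc_abort("scbc_sample_size_error", msg)
stop_degenerate <- function(msg) scbc_abort("scbc_degenerate_background_error", msg)
stop_span       <- function(msg) scbc_abort("scbc_insufficient_span_error", msg)
stop_empty      <- function(msg) scbc_abort("scbc_empty_input_error", msg)
stop_empty_signal <- function(msg) scbc_abort("scbc_empty_signal_error", msg)
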