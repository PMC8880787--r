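# Classed conditions: every user-facing failure is a pragmap_error subclass
# so the CLI can map domain errors to exit 1 and usage errors to exit 2.

pm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pragmap_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_schema    <- function(msg) pm_stop(msg, "pragmap_schema_error")
stop_format    <- function(msg) pm_stop(msg, "pragmap_format_error")
stop_reference <- function(msg) pm_stop(msg, "pragmap_reference_error")
stop_duplicate <- function(msg) pm_stop(msg, "pragmap_duplicate_error")
stop_bounds    <- function(msg) pm_stop(msg, "pragmap_bounds_error")
stop_input     <- function(msg) pm_stop(msg, "pragmap_input_error")
stop_spec      <- function(msg) pm_stop(msg, "pragmap_spec_error")
stop_usage     <- function(msg) pm_stop(msg, "pragmap_usage_error")
stop_degenerate <- function(msg) pm_stop(msg, "pragmap_degenerate_error")

pm_warn <- function(msg, class = "pragmap_warning") {
  warning(warningCondition(msg, class = class))
}

# Exact-equality morpheme matching happens after NFKC normalization so that
# full-width/half-width and composed/decomposed variants compare equal.
nfkc <- function(x) stringi::stri_trans_nfkc(x)
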