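# Structured condition helpers. Every engine error carries a class of the
# form "dockscreen_<kind>_error" so callers and tests can dispatch on kind
# rather than on message text.

ds_error <- function(kind, msg, ..., call. = FALSE) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("dockscreen_", kind, "_error"), "dockscreen_error")
  ))
}

ds_warning <- function(kind, msg) {
  warning(warningCondition(
    msg,
    class = c(paste0("dockscreen_", kind, "_warning"), "dockscreen_warning")
  ))
}
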