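# Structured conditions: every user-facing failure carries a subclass of
# "methpanel_error" so callers (and tests) can dispatch on the failure kind
# rather than on message text.

mp_abort <- function(message, class) {
  cond <- structure(
    class = c(class, "methpanel_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

mp_warn <- function(message, class) {
  cond <- structure(
    class = c(class, "methpanel_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  )
  warning(cond)
}
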