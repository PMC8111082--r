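# Named condition classes so callers can trap specific failure modes.

ccn_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("ccnet_", class), "ccnet_error")))
}

ccn_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("ccnet_", class), "ccnet_warning")))
}
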