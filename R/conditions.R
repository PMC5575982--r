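# Classed error conditions so callers (and the CLI) can distinguish
# failure modes programmatically.
phantomStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(paste0("phantom4D_", class), "phantom4D_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
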