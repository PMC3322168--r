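#' @keywords internal
sg_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

GROUP_LEVELS <- c("schizophrenic", "manic", "control", "unlabeled")
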