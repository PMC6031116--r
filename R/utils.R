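# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Abort with a stage-tagged message (used by run_pipeline so failures name
# the pipeline stage they occurred in).
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Coerce a sequence argument (character scalar, DNAString, or a length-1
# DNAStringSet) to an upper-case character scalar.
as_sequence_string <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence, got ", length(seq), call. = FALSE)
    seq <- seq[[1L]]
  }
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop("sequence must be a single character string or DNAString", call. = FALSE)
  toupper(seq)
}
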