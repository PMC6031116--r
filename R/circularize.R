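#' Circularize a linear assembly by trimming a terminal overlap
#'
#' A scaffold that represents a circular chromosome typically carries the
#' same sequence at both ends. This scans overlap lengths from
#' `max_overlap` down to `min_overlap` and accepts the longest
#' prefix/suffix match whose per-base mismatch rate is at most
#' `max_mismatch_rate`; the redundant suffix copy is trimmed. A sequence
#' with no acceptable terminal match is reported as not circular — that is
#' a result, not an error. Assembly-graph evidence is out of scope; this is
#' the sequence-level check alone.
#'
#' @param seq Character string, `DNAString`, or length-1 `DNAStringSet`.
#' @param min_overlap Smallest overlap length accepted (bp, >= 10).
#' @param max_mismatch_rate Highest tolerated mismatch fraction within the
#'   overlap (0 = exact match).
#' @param max_overlap Largest overlap length considered; defaults to half
#'   the sequence length capped at 10 kb.
#' @return A `circularization` result: list with `circular` (logical) and,
#'   when circular, `sequence` (overlap trimmed, same class as the input),
#'   `overlap` (bp) and `mismatches`.
#' @export
circularize <- function(seq, min_overlap = 50L, max_mismatch_rate = 0,
                        max_overlap = NULL) {
  s <- as_sequence_string(seq)
  L <- nchar(s)
  if (min_overlap < 10L)
    stop("min_overlap must be at least 10 bp", call. = FALSE)
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 1)
    stop("max_mismatch_rate must lie in [0, 1)", call. = FALSE)
  if (is.null(max_overlap)) max_overlap <- min(L %/% 2L, 10000L)
  max_overlap <- min(max_overlap, L %/% 2L)
  if (max_overlap < min_overlap)
    return(structure(list(circular = FALSE), class = "circularization"))

  head_v <- utf8ToInt(substr(s, 1L, max_overlap))
  tail_v <- utf8ToInt(substr(s, L - max_overlap + 1L, L))
  for (k in seq.int(max_overlap, min_overlap)) {
    mm <- sum(head_v[seq_len(k)] != tail_v[(max_overlap - k + 1L):max_overlap])
    if (mm <= k * max_mismatch_rate) {
      trimmed <- substr(s, 1L, L - k)
      out <- if (is.character(seq)) trimmed else Biostrings::DNAString(trimmed)
      return(structure(
        list(circular = TRUE, sequence = out, overlap = k, mismatches = mm),
        class = "circularization"))
    }
  }
  structure(list(circular = FALSE), class = "circularization")
}

#' @export
print.circularization <- function(x, ...) {
  if (x$circular)
    cat(sprintf("circular: terminal overlap of %d bp (%d mismatches) trimmed\n",
                x$overlap, x$mismatches))
  else cat("not circular: no acceptable terminal overlap\n")
  invisible(x)
}
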