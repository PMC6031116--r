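#' Windowed GC skew and cumulative GC skew of a genome
#'
#' Computes per-window GC skew \eqn{(G - C)/(G + C)} in sliding windows and
#' its running sum (cumulative skew). Across a correctly assembled circular
#' bacterial chromosome replicating bidirectionally, the cumulative curve
#' shows a single trough at the replication origin and a single peak at the
#' terminus, which makes it a standard check of a circularized assembly.
#'
#' Non-G/C characters (A, T, N and ambiguity codes) contribute to neither
#' count; a window with no G or C at all has skew 0. In circular mode
#' windows wrap across the sequence end and window positions are reported
#' in unwrapped coordinates (window start + half window, so they stay
#' strictly increasing and the last few may exceed the sequence length).
#'
#' @param seq Character string, `DNAString`, or length-1 `DNAStringSet`.
#' @param window Window size in bp (default 1000).
#' @param step Distance between window starts in bp (default 10).
#' @param circular Wrap windows across the sequence end?
#' @return A `skew_profile`: `data.frame` with columns `position` (1-based
#'   window centre), `skew` and `cumulative`; attributes `window`, `step`,
#'   `seq_length`, `circular`.
#' @examples
#' gc_skew("GGGGCC", window = 6, step = 6)$skew # (4-2)/(4+2) = 1/3
#' @export
gc_skew <- function(seq, window = 1000L, step = 10L, circular = FALSE) {
  s <- as_sequence_string(seq)
  L <- nchar(s)
  if (window < 1L || step < 1L)
    stop("window and step must be >= 1", call. = FALSE)
  if (!circular && window > L)
    stop("window (", window, ") exceeds sequence length (", L,
         ") in linear mode", call. = FALSE)
  x <- utf8ToInt(s)
  isG <- as.integer(x == 71L)  # 'G'
  isC <- as.integer(x == 67L)  # 'C'
  if (circular) {
    wrap <- min(window - 1L, L)
    isG <- c(isG, isG[seq_len(wrap)])
    isC <- c(isC, isC[seq_len(wrap)])
    starts <- seq.int(1L, L, by = step)
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
  }
  cg <- c(0, cumsum(isG))
  cc <- c(0, cumsum(isC))
  G <- cg[starts + window] - cg[starts]
  C <- cc[starts + window] - cc[starts]
  tot <- G + C
  skew <- ifelse(tot == 0, 0, (G - C) / tot)
  structure(
    data.frame(position = starts + window %/% 2L,
               skew = skew, cumulative = cumsum(skew)),
    window = window, step = step, seq_length = L, circular = circular,
    class = c("skew_profile", "data.frame")
  )
}

#' Write a skew profile to TSV
#' @param profile A `skew_profile`.
#' @param path Output path.
#' @export
write_skew_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Predict replication origin and terminus from cumulative GC skew
#'
#' Under the usual leading-strand G excess, the cumulative GC skew is
#' minimal at the replication origin and maximal at the terminus; set
#' `invert = TRUE` for organisms with the opposite strand bias. Ties are
#' broken toward the smallest coordinate.
#'
#' @param profile A `skew_profile` from [gc_skew()].
#' @param invert Swap the min/max convention.
#' @return An `ori_ter_call` with fields `ori_pos`, `ter_pos` (1-based) and
#'   `amplitude` (max - min of the cumulative curve).
#' @export
predict_ori_ter <- function(profile, invert = FALSE) {
  if (nrow(profile) == 0L) stop("empty skew profile", call. = FALSE)
  cum <- profile$cumulative
  amp <- max(cum) - min(cum)
  if (amp == 0)
    stop("flat cumulative skew profile: no origin/terminus signal",
         call. = FALSE)
  i_min <- which.min(cum)
  i_max <- which.max(cum)
  if (invert) { tmp <- i_min; i_min <- i_max; i_max <- tmp }
  L <- attr(profile, "seq_length")
  wrap1 <- function(p) if (!is.null(L)) (p - 1L) %% L + 1L else p
  structure(
    list(ori_pos = wrap1(profile$position[i_min]),
         ter_pos = wrap1(profile$position[i_max]),
         amplitude = amp),
    class = "ori_ter_call"
  )
}

#' @export
print.ori_ter_call <- function(x, ...) {
  cat(sprintf("replication origin: %d bp, terminus: %d bp (cumulative-skew amplitude %.3f)\n",
              x$ori_pos, x$ter_pos, x$amplitude))
  invisible(x)
}

#' Rotate a circular sequence so it starts at the replication origin
#'
#' @param seq Character string, `DNAString`, or length-1 `DNAStringSet`.
#' @param ori_pos 1-based start coordinate (typically an `ori_pos` from
#'   [predict_ori_ter()]).
#' @return The rotated sequence, same class as the input (`DNAStringSet`
#'   input returns a `DNAString`).
#' @export
rotate_to_origin <- function(seq, ori_pos) {
  s <- as_sequence_string(seq)
  L <- nchar(s)
  if (!is.numeric(ori_pos) || length(ori_pos) != 1L ||
      ori_pos < 1L || ori_pos > L)
    stop("origin position ", ori_pos, " outside sequence [1, ", L, "]",
         call. = FALSE)
  ori_pos <- as.integer(ori_pos)
  out <- if (ori_pos == 1L) s
         else paste0(substr(s, ori_pos, L), substr(s, 1L, ori_pos - 1L))
  if (is.character(seq)) out else Biostrings::DNAString(out)
}
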