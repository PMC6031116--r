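#' Light/middle/heavy density bin scheme
#'
#' A bin scheme is three ordered, non-overlapping density intervals (g/mL)
#' interpreted as unenriched (light), partially 13C-enriched (middle) and
#' highly 13C-enriched (heavy) DNA. Middle and/or heavy may be empty (NULL)
#' when a gradient shows no enrichment signal. Intervals are closed; small
#' gaps between printed cutoffs (fraction boundaries are discrete) are
#' tolerated up to `gap_tol` and resolved at assignment time by proximity.
#'
#' @param light,middle,heavy Numeric `c(lo, hi)` intervals in g/mL, or NULL
#'   for an empty bin (light must be non-empty).
#' @param gap_tol Largest allowed gap between consecutive intervals (g/mL).
#' @return A `bin_scheme`.
#' @seealso [sip_bin_scheme()] for the conventional soil-SIP cutoffs.
#' @export
bin_scheme <- function(light, middle = NULL, heavy = NULL, gap_tol = 0.0015) {
  check_iv <- function(iv, nm) {
    if (is.null(iv)) return(NULL)
    if (!is.numeric(iv) || length(iv) != 2L || any(!is.finite(iv)))
      stop("bin '", nm, "' must be a numeric c(lo, hi) interval", call. = FALSE)
    if (iv[1L] > iv[2L])
      stop("bin '", nm, "' has lo > hi: ", iv[1L], " > ", iv[2L], call. = FALSE)
    iv
  }
  light <- check_iv(light, "light")
  if (is.null(light)) stop("light bin is required", call. = FALSE)
  middle <- check_iv(middle, "middle")
  heavy <- check_iv(heavy, "heavy")
  ivs <- Filter(Negate(is.null), list(light = light, middle = middle,
                                      heavy = heavy))
  if (length(ivs) > 1L) {
    for (i in seq_len(length(ivs) - 1L)) {
      gap <- ivs[[i + 1L]][1L] - ivs[[i]][2L]
      if (gap < 0)
        stop("bins '", names(ivs)[i], "' and '", names(ivs)[i + 1L],
             "' overlap", call. = FALSE)
      if (gap > gap_tol)
        stop("gap of ", format(gap), " g/mL between bins '", names(ivs)[i],
             "' and '", names(ivs)[i + 1L], "' exceeds gap_tol = ", gap_tol,
             call. = FALSE)
    }
  }
  structure(list(light = light, middle = middle, heavy = heavy),
            gap_tol = gap_tol, class = "bin_scheme")
}

#' Conventional soil-SIP density cutoffs
#'
#' The fixed cutoffs used for binning soil SIP gradients: light
#' 1.692-1.737, middle 1.738-1.746, heavy 1.747-1.765 g/mL. The 0.001 g/mL
#' gaps reflect that the printed cutoffs are discrete fraction boundaries;
#' densities falling inside a gap are assigned to the nearer bin.
#'
#' @return A `bin_scheme`.
#' @export
sip_bin_scheme <- function() {
  bin_scheme(light = c(1.692, 1.737), middle = c(1.738, 1.746),
             heavy = c(1.747, 1.765))
}

#' @export
print.bin_scheme <- function(x, ...) {
  fmt <- function(iv, nm) {
    if (is.null(iv)) cat("  ", nm, ": (empty)\n", sep = "")
    else cat(sprintf("  %s: %.4f-%.4f g/mL\n", nm, iv[1L], iv[2L]))
  }
  cat("bin_scheme\n")
  fmt(x$light, "light"); fmt(x$middle, "middle"); fmt(x$heavy, "heavy")
  if (isTRUE(attr(x, "empty_heavy_warning")))
    cat("  (no density satisfied the heavy rule)\n")
  invisible(x)
}

# Distance from a density to a closed interval (0 if inside).
interval_distance <- function(d, iv) {
  ifelse(d < iv[1L], iv[1L] - d, ifelse(d > iv[2L], d - iv[2L], 0))
}

#' Assign gradient fractions to density bins
#'
#' Each fraction is labeled by the (closed) bin interval containing its
#' density. A density falling in the gap between two printed cutoffs goes to
#' the nearer interval, ties to the lighter bin; densities outside the
#' scheme's overall span are labeled `unbinned`. Per-bin pooled DNA masses
#' are summed from the fraction concentrations.
#'
#' @param profile A `gradient_profile`.
#' @param scheme A `bin_scheme`.
#' @return A `binned_profile`: the profile `data.frame` with a `bin` factor
#'   column, plus `scheme` and `pooled_mass` attributes.
#' @export
assign_bins <- function(profile, scheme = sip_bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  labels <- c("light", "middle", "heavy")
  ivs <- scheme[labels]
  present <- labels[!vapply(ivs, is.null, logical(1))]
  span <- range(unlist(ivs[present]))
  gap_tol <- attr(scheme, "gap_tol")

  bin_one <- function(d) {
    dists <- vapply(present, function(nm) interval_distance(d, ivs[[nm]]),
                    numeric(1))
    inside <- present[dists == 0]
    if (length(inside)) return(inside[1L])
    if (d < span[1L] || d > span[2L]) return("unbinned")
    # in a gap between printed cutoffs: nearest interval, ties to lighter
    present[which.min(dists)]
  }
  bin <- vapply(profile$density, bin_one, character(1))
  out <- profile
  out$bin <- factor(bin, levels = c(labels, "unbinned"))
  pooled <- tapply(out$dna_conc, out$bin, sum, default = 0)
  structure(out, scheme = scheme, pooled_mass = pooled,
            class = c("binned_profile", class(profile)))
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("binned_profile '%s': %d fractions\n",
              attr(x, "sample_id"), nrow(x)))
  pm <- attr(x, "pooled_mass")
  for (nm in names(pm))
    cat(sprintf("  %-8s n = %2d  pooled mass = %.4g\n", nm,
                sum(x$bin == nm), pm[[nm]]))
  invisible(x)
}

#' Derive light/middle/heavy cutoffs by comparing treatment to control
#'
#' Data-driven binning of a labeled (treatment) gradient against its
#' unlabeled (control) gradient, mirroring the qualitative procedure of
#' comparing the two density profiles. Working on per-fraction DNA masses
#' expressed as fractions of each sample's total, and scanning densities
#' above the control profile's mode (below it, both tails vanish and the
#' rules would fire spuriously):
#'
#' * heavy lower bound: the smallest density at which the control carries
#'   less than `epsilon` of its mass while the treatment still carries at
#'   least `epsilon`;
#' * middle lower bound: the smallest density at which the treatment's
#'   relative mass exceeds the control's by more than `delta`;
#' * light: the remaining lower range.
#'
#' The control profile is linearly interpolated onto the treatment's
#' density grid (zero outside its observed range). The returned scheme
#' covers the full observed density span with contiguous intervals; when no
#' density satisfies a rule the corresponding bin is empty, and an empty
#' heavy bin sets the `empty_heavy_warning` attribute.
#'
#' @param treatment,control `gradient_profile`s spanning overlapping
#'   density ranges.
#' @param epsilon Relative-mass threshold for the heavy rule (fraction of a
#'   sample's total DNA mass), in (0, 1\].
#' @param delta Excess-mass threshold for the middle rule, in (0, 1\].
#' @return A `bin_scheme`.
#' @export
auto_bin <- function(treatment, control, epsilon = 0.05, delta = 0.02) {
  if (epsilon <= 0 || epsilon > 1 || delta <= 0 || delta > 1)
    stop("epsilon and delta must lie in (0, 1]", call. = FALSE)
  rt <- range(treatment$density); rc <- range(control$density)
  if (rt[2L] < rc[1L] || rc[2L] < rt[1L])
    stop("treatment and control gradients span disjoint density ranges",
         call. = FALSE)

  d_t <- sort(treatment$density)
  rel_t <- treatment$dna_conc[order(treatment$density)] /
    sum(treatment$dna_conc)
  ord_c <- order(control$density)
  d_c <- control$density[ord_c]
  rel_c_own <- control$dna_conc[ord_c] / sum(control$dna_conc)
  rel_c <- stats::approx(d_c, rel_c_own, xout = d_t,
                         yleft = 0, yright = 0, ties = mean)$y
  mode_c <- d_c[which.max(rel_c_own)]

  above <- d_t > mode_c
  heavy_ok <- above & rel_c < epsilon & rel_t >= epsilon
  middle_ok <- above & (rel_t - rel_c) > delta
  heavy_lo <- if (any(heavy_ok)) min(d_t[heavy_ok]) else NA_real_
  middle_lo <- if (any(middle_ok)) min(d_t[middle_ok]) else NA_real_
  if (!is.na(heavy_lo) && !is.na(middle_lo) && middle_lo > heavy_lo)
    middle_lo <- heavy_lo

  span <- range(c(rt, rc))
  scheme <- if (is.na(middle_lo) && is.na(heavy_lo)) {
    bin_scheme(light = span)
  } else if (is.na(heavy_lo)) {
    bin_scheme(light = c(span[1L], middle_lo),
               middle = c(middle_lo, span[2L]))
  } else if (is.na(middle_lo)) {
    bin_scheme(light = c(span[1L], heavy_lo),
               heavy = c(heavy_lo, span[2L]))
  } else {
    bin_scheme(light = c(span[1L], middle_lo),
               middle = c(middle_lo, heavy_lo),
               heavy = c(heavy_lo, span[2L]))
  }
  if (is.na(heavy_lo)) {
    attr(scheme, "empty_heavy_warning") <- TRUE
    warning("no density satisfied the heavy rule; heavy bin left empty",
            call. = FALSE)
  }
  attr(scheme, "thresholds") <- c(epsilon = epsilon, delta = delta)
  scheme
}
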