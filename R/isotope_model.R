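#' Buoyant-density model for GC content and 13C labeling
#'
#' Constructs the set of physical constants that tie DNA base composition and
#' isotopic labeling to equilibrium buoyant density in a CsCl gradient.
#' The GC dependence follows the classical Schildkraut linear relation
#' \eqn{\rho = 1.660 + 0.098 \cdot GC} (g/mL, GC as a fraction), and full
#' substitution of \eqn{^{12}}C by \eqn{^{13}}C adds a fixed density shift
#' (0.036 g/mL by default, the standard DNA-SIP value). Fraction densities
#' measured by refractometry are converted with a linear CsCl calibration
#' line \eqn{\rho = a \cdot RI + b}; calibrations are instrument-specific,
#' so both coefficients are settable.
#'
#' @param gc_slope Density increase per unit GC fraction (g/mL).
#' @param gc_intercept Density of GC = 0 DNA (g/mL).
#' @param max_shift_13c Buoyant-density increase for 100 atom\% 13C labeling
#'   (g/mL).
#' @param ri_slope,ri_intercept Coefficients of the refractive-index to
#'   density calibration line for CsCl at the calibration temperature.
#' @return An object of class `isotope_model`.
#' @examples
#' m <- isotope_model()
#' gc_to_density(0.4995, m) # ~ 1.71 g/mL
#' @export
isotope_model <- function(gc_slope = 0.098, gc_intercept = 1.660,
                          max_shift_13c = 0.036,
                          ri_slope = 10.8601, ri_intercept = -13.4974) {
  for (nm in c("gc_slope", "gc_intercept", "max_shift_13c",
               "ri_slope", "ri_intercept")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("isotope_model: '", nm, "' must be a single finite number")
  }
  if (gc_slope <= 0) stop("isotope_model: gc_slope must be > 0")
  if (max_shift_13c <= 0) stop("isotope_model: max_shift_13c must be > 0")
  if (ri_slope <= 0) stop("isotope_model: ri_slope must be > 0")
  structure(
    list(gc_slope = gc_slope, gc_intercept = gc_intercept,
         max_shift_13c = max_shift_13c,
         ri_slope = ri_slope, ri_intercept = ri_intercept),
    class = "isotope_model"
  )
}

#' @export
print.isotope_model <- function(x, ...) {
  cat("isotope_model: rho = ", format(x$gc_intercept), " + ",
      format(x$gc_slope), " * GC  (+ ", format(x$max_shift_13c),
      " * AFE g/mL at full 13C labeling)\n", sep = "")
  cat("  RI calibration: rho = ", format(x$ri_slope), " * RI ",
      ifelse(x$ri_intercept < 0, "- ", "+ "),
      format(abs(x$ri_intercept)), "\n", sep = "")
  invisible(x)
}

check_gc <- function(gc) {
  if (!is.numeric(gc) || any(!is.finite(gc)) || any(gc < 0 | gc > 1))
    stop("GC fraction out of [0, 1]: ",
         paste(gc[!is.finite(gc) | gc < 0 | gc > 1], collapse = ", "),
         call. = FALSE)
  gc
}

check_afe <- function(afe) {
  if (!is.numeric(afe) || any(!is.finite(afe)) || any(afe < 0 | afe > 1))
    stop("atom-fraction excess out of [0, 1]: ",
         paste(afe[!is.finite(afe) | afe < 0 | afe > 1], collapse = ", "),
         call. = FALSE)
  afe
}

#' Buoyant density of unlabeled DNA from its GC content
#'
#' @param gc GC content as a fraction in \[0, 1\] (vectorized).
#' @param model An [isotope_model()].
#' @return Buoyant density in g/mL.
#' @examples
#' gc_to_density(0.4995) # 1.708951
#' @export
gc_to_density <- function(gc, model = isotope_model()) {
  check_gc(gc)
  model$gc_intercept + model$gc_slope * gc
}

#' Buoyant density of partially 13C-labeled DNA
#'
#' Forward model: the density of natural-abundance DNA of the given GC plus
#' a shift proportional to the atom-fraction excess of 13C.
#'
#' @inheritParams gc_to_density
#' @param afe Atom-fraction excess of 13C in \[0, 1\] (1 = fully labeled).
#' @return Buoyant density in g/mL.
#' @export
density_from_enrichment <- function(gc, afe, model = isotope_model()) {
  check_afe(afe)
  gc_to_density(gc, model) + afe * model$max_shift_13c
}

new_enrichment_estimate <- function(afe, afe_lower, afe_upper,
                                    observed_density, unlabeled_density) {
  structure(
    list(afe = afe, afe_lower = afe_lower, afe_upper = afe_upper,
         observed_density = observed_density,
         unlabeled_density = unlabeled_density),
    class = "enrichment_estimate"
  )
}

#' @export
print.enrichment_estimate <- function(x, ...) {
  cat(sprintf("13C enrichment estimate: AFE = %.3f [%.3f, %.3f]\n",
              x$afe, x$afe_lower, x$afe_upper))
  cat(sprintf("  observed density %.4f g/mL vs unlabeled %.4f g/mL\n",
              x$observed_density, x$unlabeled_density))
  invisible(x)
}

check_density_plausible <- function(density) {
  if (!is.numeric(density) || any(!is.finite(density)) ||
      any(density < 1.60 | density > 1.85))
    stop("density outside the plausible CsCl range [1.60, 1.85] g/mL: ",
         paste(density[!is.finite(density) | density < 1.60 | density > 1.85],
               collapse = ", "),
         call. = FALSE)
  density
}

#' Estimate 13C enrichment from an observed buoyant density
#'
#' Inverts [density_from_enrichment()]: the excess of the observed density
#' over the density expected for unlabeled DNA of the same GC content,
#' divided by the full-labeling shift, clamped to \[0, 1\]. DNA observed at
#' or below its unlabeled density is reported as unenriched.
#'
#' @param observed_density Observed buoyant density in g/mL (must lie in the
#'   physically plausible CsCl range \[1.60, 1.85\]).
#' @inheritParams gc_to_density
#' @return An `enrichment_estimate` with fields `afe`, `afe_lower`,
#'   `afe_upper` (equal to `afe` for a point estimate), `observed_density`
#'   and `unlabeled_density`.
#' @examples
#' # genome at 49.95% GC recovered from a 1.737 g/mL fraction:
#' enrichment_from_density(1.737, gc = 0.4995)
#' @export
enrichment_from_density <- function(observed_density, gc,
                                    model = isotope_model()) {
  check_density_plausible(observed_density)
  unlabeled <- gc_to_density(gc, model)
  afe <- clamp01((observed_density - unlabeled) / model$max_shift_13c)
  new_enrichment_estimate(afe, afe, afe, observed_density, unlabeled)
}

#' Estimate 13C enrichment from a density interval
#'
#' For a genome detected across a density interval (for instance the bin it
#' was mainly recovered from) rather than at a point: the lower and upper
#' interval bounds give lower and upper AFE bounds, and the point estimate
#' is their midpoint after clamping.
#'
#' @param lo,hi Interval bounds in g/mL, `lo <= hi`.
#' @inheritParams gc_to_density
#' @return An `enrichment_estimate`.
#' @export
enrichment_from_density_interval <- function(lo, hi, gc,
                                             model = isotope_model()) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi)
    stop("density interval bounds out of order: lo = ", lo, ", hi = ", hi,
         call. = FALSE)
  lo_est <- enrichment_from_density(lo, gc, model)
  hi_est <- enrichment_from_density(hi, gc, model)
  new_enrichment_estimate(
    afe = (lo_est$afe + hi_est$afe) / 2,
    afe_lower = lo_est$afe, afe_upper = hi_est$afe,
    observed_density = (lo + hi) / 2,
    unlabeled_density = lo_est$unlabeled_density
  )
}

#' Convert refractive index to CsCl solution density (and back)
#'
#' Linear calibration line for refractometric density measurement of CsCl
#' gradient fractions. `density_to_ri` is the exact inverse.
#'
#' @param ri Refractive index reading, in \[1.3, 1.5\] (vectorized).
#' @param density Density in g/mL.
#' @inheritParams gc_to_density
#' @return Density in g/mL (`ri_to_density`) or refractive index
#'   (`density_to_ri`).
#' @export
ri_to_density <- function(ri, model = isotope_model()) {
  if (!is.numeric(ri) || any(!is.finite(ri)) || any(ri < 1.3 | ri > 1.5))
    stop("refractive index outside [1.3, 1.5]: ",
         paste(ri[!is.finite(ri) | ri < 1.3 | ri > 1.5], collapse = ", "),
         call. = FALSE)
  model$ri_slope * ri + model$ri_intercept
}

#' @rdname ri_to_density
#' @export
density_to_ri <- function(density, model = isotope_model()) {
  if (!is.numeric(density) || any(!is.finite(density)))
    stop("density must be finite", call. = FALSE)
  (density - model$ri_intercept) / model$ri_slope
}
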