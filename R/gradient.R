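#' Construct a density-gradient fraction profile
#'
#' A gradient profile holds the ordered fraction records of one CsCl
#' ultracentrifugation run: fraction id (ordinal from the pierced tube
#' bottom, so densest first), buoyant density (g/mL), recovered DNA amount,
#' and optionally the sequencing depth of the fraction's library. Fractions
#' supplied in ascending density order are canonicalized to descending.
#'
#' @param fractions `data.frame` with columns `fraction_id`, `density`,
#'   `dna_conc` and optionally `seq_depth`.
#' @param sample_id Character label for the sample.
#' @param role `"treatment"` (labeled sample) or `"control"`
#'   (natural-abundance sample).
#' @param density_tol Tolerance for monotonicity violations in the supplied
#'   densities (g/mL); anything worse is a format error.
#' @return A `gradient_profile`: the fraction `data.frame` ordered by
#'   decreasing density, with `sample_id` and `role` attributes.
#' @export
gradient_profile <- function(fractions, sample_id = "sample",
                             role = c("treatment", "control"),
                             density_tol = 1e-6) {
  role <- match.arg(role)
  req <- c("fraction_id", "density", "dna_conc")
  miss <- setdiff(req, names(fractions))
  if (length(miss))
    stop("gradient profile is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(fractions) < 3L)
    stop("gradient profile needs at least 3 fractions, got ", nrow(fractions),
         call. = FALSE)
  if (any(!is.finite(fractions$density) | fractions$density <= 0)) {
    bad <- which(!is.finite(fractions$density) | fractions$density <= 0)[1L]
    stop("non-positive density at row ", bad, call. = FALSE)
  }
  if (any(!is.finite(fractions$dna_conc) | fractions$dna_conc < 0)) {
    bad <- which(!is.finite(fractions$dna_conc) | fractions$dna_conc < 0)[1L]
    stop("negative DNA concentration at row ", bad, call. = FALSE)
  }
  d <- fractions$density
  dd <- diff(d)
  if (!(all(dd <= density_tol) || all(dd >= -density_tol))) {
    bad <- if (sum(dd > 0) >= sum(dd < 0)) which(dd < -density_tol)[1L]
           else which(dd > density_tol)[1L]
    stop("densities are not monotone: violation between rows ", bad, " and ",
         bad + 1L, call. = FALSE)
  }
  fractions <- fractions[order(fractions$density, decreasing = TRUE), ,
                         drop = FALSE]
  rownames(fractions) <- NULL
  structure(fractions, sample_id = sample_id, role = role,
            class = c("gradient_profile", "data.frame"))
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("gradient_profile '%s' (%s): %d fractions, %.3f-%.3f g/mL\n",
              attr(x, "sample_id"), attr(x, "role"), nrow(x),
              min(x$density), max(x$density)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more fractions\n", sep = "")
  invisible(x)
}

#' Read a gradient fraction table from TSV
#'
#' Expects a tab-separated table with header columns `fraction_id`,
#' `density` (g/mL) or `refractive_index`, `dna_conc`, and optionally
#' `seq_depth`. When only a refractive index is supplied, densities are
#' computed through the model's CsCl calibration line.
#'
#' @param path Path to the TSV file.
#' @inheritParams gradient_profile
#' @param model [isotope_model()] used for refractive-index conversion.
#' @return A `gradient_profile`.
#' @export
load_profile <- function(path, sample_id = basename(path),
                         role = c("treatment", "control"),
                         model = isotope_model()) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("fraction table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"density" %in% names(tab)) {
    if (!"refractive_index" %in% names(tab))
      stop("fraction table needs a 'density' or 'refractive_index' column: ",
           path, call. = FALSE)
    tab$density <- ri_to_density(tab$refractive_index, model)
  }
  gradient_profile(tab, sample_id = sample_id, role = role)
}

#' Write a gradient profile to TSV
#' @param profile A `gradient_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale per-fraction genome coverage to a common sequencing depth
#'
#' Raw coverage of a genome in each fraction's library depends on how deeply
#' that library was sequenced; rescaling every fraction to a common
#' reference depth (`normalized = raw * reference_depth / seq_depth`) makes
#' coverages comparable across fractions. The default reference is the
#' minimum depth across fractions, so normalized coverage never exceeds raw.
#'
#' @param coverage `data.frame` with columns `genome_id`, `fraction_id`,
#'   `coverage` and `seq_depth` (total sequenced bases of the fraction's
#'   library).
#' @param reference_depth Depth every fraction is rescaled to; defaults to
#'   `min(coverage$seq_depth)`.
#' @return The input `data.frame` with a `normalized` column added.
#' @export
normalize_coverage <- function(coverage, reference_depth = NULL) {
  req <- c("genome_id", "fraction_id", "coverage", "seq_depth")
  miss <- setdiff(req, names(coverage))
  if (length(miss))
    stop("coverage table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(coverage$seq_depth) | coverage$seq_depth <= 0)) {
    bad <- coverage$fraction_id[!is.finite(coverage$seq_depth) |
                                  coverage$seq_depth <= 0][1L]
    stop("non-positive sequencing depth for fraction ", bad, call. = FALSE)
  }
  if (any(coverage$coverage < 0))
    stop("negative raw coverage", call. = FALSE)
  if (is.null(reference_depth)) reference_depth <- min(coverage$seq_depth)
  coverage$normalized <- coverage$coverage * reference_depth / coverage$seq_depth
  attr(coverage, "reference_depth") <- reference_depth
  attr(coverage, "normalization") <- "total sequenced bases per fraction library"
  coverage
}

#' Coverage-weighted density centroid of a genome across the gradient
#'
#' The buoyant density at which a genome is centred, estimated as the mean
#' of fraction densities weighted by the genome's (normalized, if present)
#' coverage in each fraction. Feeding this into
#' [enrichment_from_density()] gives the genome's isotope-enrichment
#' estimate.
#'
#' @param coverage Coverage table as for [normalize_coverage()]; rows for
#'   one genome. If a `normalized` column is present it is used as the
#'   weight, otherwise raw `coverage`.
#' @param profile The `gradient_profile` the coverages refer to (matched by
#'   `fraction_id`).
#' @return Density centroid in g/mL.
#' @export
genome_density_centroid <- function(coverage, profile) {
  w <- if ("normalized" %in% names(coverage)) coverage$normalized
       else coverage$coverage
  idx <- match(coverage$fraction_id, profile$fraction_id)
  if (anyNA(idx))
    stop("coverage refers to fraction_id(s) absent from the profile: ",
         paste(unique(coverage$fraction_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (all(w <= 0))
    stop("cannot estimate a density centroid: coverage is zero in every fraction",
         call. = FALSE)
  sum(w * profile$density[idx]) / sum(w)
}
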