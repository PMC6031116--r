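#' Define a simulated community of taxa for a SIP gradient
#'
#' Each taxon contributes DNA mass to the gradient in proportion to its
#' relative abundance; its band centre is set by its GC content and 13C
#' atom-fraction excess through [density_from_enrichment()].
#'
#' @param taxon_id Character ids.
#' @param abundance Relative DNA mass fractions; must sum to 1 (1e-9).
#' @param gc GC fractions.
#' @param afe Atom-fraction excess of 13C per taxon, in \[0, 1\].
#' @param genome_length Genome lengths in bp.
#' @return `data.frame` of class `sim_taxa`.
#' @export
sim_taxa <- function(taxon_id, abundance, gc, afe, genome_length) {
  n <- length(taxon_id)
  stopifnot(length(abundance) == n, length(gc) == n, length(afe) == n,
            length(genome_length) == n)
  if (abs(sum(abundance) - 1) > 1e-9)
    stop("taxon abundances must sum to 1, got ", format(sum(abundance)),
         call. = FALSE)
  check_gc(gc); check_afe(afe)
  if (any(genome_length < 1)) stop("genome_length must be positive")
  structure(
    data.frame(taxon_id = taxon_id, abundance = abundance, gc = gc,
               afe = afe, genome_length = genome_length,
               stringsAsFactors = FALSE),
    class = c("sim_taxa", "data.frame")
  )
}

#' Configuration of a simulated CsCl gradient
#'
#' Defaults emulate a typical soil-SIP run: ~32 fractions collected from a
#' bottom-pierced tube spanning 1.692-1.765 g/mL, with each taxon's DNA
#' spread around its band centre as a Gaussian with standard deviation
#' `band_sd` (0.003 g/mL — wide enough that a taxon's mass lands in a
#' handful of adjacent fractions, as real gradient profiles show).
#'
#' @param n_fractions Number of fractions (>= 3).
#' @param density_min,density_max Gradient density span in g/mL.
#' @param band_sd Gaussian band-spread standard deviation in g/mL.
#' @param total_dna_mass Total DNA mass loaded (arbitrary units).
#' @param noise_sd Standard deviation of multiplicative log-normal noise on
#'   per-fraction taxon masses (0 = noise-free).
#' @param seed Integer seed; all randomness of the simulator flows from it.
#' @param model [isotope_model()] used for band centres.
#' @return A `gradient_config` list.
#' @export
gradient_config <- function(n_fractions = 32L, density_min = 1.692,
                            density_max = 1.765, band_sd = 0.003,
                            total_dna_mass = 100, noise_sd = 0, seed = 1L,
                            model = isotope_model()) {
  if (n_fractions < 3L) stop("n_fractions must be >= 3", call. = FALSE)
  if (density_min >= density_max)
    stop("density_min must be below density_max", call. = FALSE)
  if (band_sd <= 0) stop("band_sd must be > 0", call. = FALSE)
  structure(
    list(n_fractions = as.integer(n_fractions), density_min = density_min,
         density_max = density_max, band_sd = band_sd,
         total_dna_mass = total_dna_mass, noise_sd = noise_sd,
         seed = as.integer(seed), model = model),
    class = "gradient_config"
  )
}

#' Simulate a density gradient and per-fraction genome coverages
#'
#' Forward model of an isopycnic CsCl separation: the gradient span is cut
#' into `n_fractions` equal-width density intervals (densest collected
#' first); each taxon's band centre is `density_from_enrichment(gc, afe)`
#' and its DNA mass is apportioned to fractions by integrating a Gaussian
#' of sd `band_sd` over each interval. Fraction DNA concentration sums the
#' taxon masses; per-taxon coverage in a fraction is proportional to taxon
#' mass over genome length, scaled so the highest coverage in the table is
#' `peak_coverage` (a realism anchor, ~15x for a well-sampled genome).
#' Mass falling outside the gradient span is truncated and reported.
#'
#' @param taxa A [sim_taxa()] table.
#' @param config A [gradient_config()].
#' @param sample_id,role Passed to [gradient_profile()].
#' @param peak_coverage Coverage assigned to the best-covered
#'   taxon/fraction combination.
#' @param seq_depth Sequencing depth (bases) recorded per fraction library.
#' @return List with `profile` (a `gradient_profile`), `coverage`
#'   (`data.frame`: `genome_id`, `fraction_id`, `coverage`, `seq_depth`)
#'   and `truncated` (per-taxon mass fraction lost outside the span).
#' @export
simulate_gradient <- function(taxa, config = gradient_config(),
                              sample_id = "sim", role = "treatment",
                              peak_coverage = 15, seq_depth = 1e9) {
  stopifnot(inherits(taxa, "sim_taxa"), inherits(config, "gradient_config"))
  bounds <- seq(config$density_min, config$density_max,
                length.out = config$n_fractions + 1L)
  lo <- bounds[-length(bounds)]
  hi <- bounds[-1L]
  centres <- density_from_enrichment(taxa$gc, taxa$afe, config$model)

  out_of_range <- centres < config$density_min | centres > config$density_max
  if (any(out_of_range))
    warning("band centre(s) outside the gradient span for taxa: ",
            paste(taxa$taxon_id[out_of_range], collapse = ", "),
            "; their mass is truncated", call. = FALSE)

  # mass of taxon j in fraction i: abundance_j * total * Phi-mass of the
  # band over the fraction's density interval
  mass <- withr::with_seed(config$seed, {
    m <- vapply(seq_len(nrow(taxa)), function(j) {
      taxa$abundance[j] * config$total_dna_mass *
        (stats::pnorm(hi, centres[j], config$band_sd) -
           stats::pnorm(lo, centres[j], config$band_sd))
    }, numeric(config$n_fractions))
    if (config$noise_sd > 0)
      m <- m * exp(stats::rnorm(length(m), 0, config$noise_sd))
    m
  })
  mass <- matrix(mass, nrow = config$n_fractions)

  in_span <- stats::pnorm(config$density_max, centres, config$band_sd) -
    stats::pnorm(config$density_min, centres, config$band_sd)
  truncated <- stats::setNames(1 - in_span, taxa$taxon_id)

  # densest fraction first (bottom-pierced tube)
  ord <- order((lo + hi) / 2, decreasing = TRUE)
  profile <- gradient_profile(
    data.frame(fraction_id = seq_len(config$n_fractions),
               density = ((lo + hi) / 2)[ord],
               dna_conc = rowSums(mass)[ord],
               seq_depth = seq_depth),
    sample_id = sample_id, role = role
  )

  cov_raw <- sweep(mass, 2L, taxa$genome_length, "/")
  scale <- if (max(cov_raw) > 0) peak_coverage / max(cov_raw) else 1
  coverage <- data.frame(
    genome_id = rep(taxa$taxon_id, each = config$n_fractions),
    fraction_id = rep(seq_len(config$n_fractions), times = nrow(taxa)),
    coverage = as.vector(cov_raw[ord, , drop = FALSE]) * scale,
    seq_depth = seq_depth,
    stringsAsFactors = FALSE
  )
  list(profile = profile, coverage = coverage, truncated = truncated)
}

#' Simulate a genome with controlled GC content and replication skew
#'
#' Generates a random sequence whose two halves carry opposite G/C biases,
#' emulating the strand asymmetry left by bidirectional replication: the
#' first half over-uses C and the second half over-uses G by
#' `skew_amplitude`, so the cumulative GC skew has its trough (predicted
#' origin) at the halfway switch point and its peak (terminus) at the
#' sequence ends. Optionally lays out non-overlapping gene intervals with
#' annotation-status and CAZy-family columns. Output is deterministic per
#' seed.
#'
#' @param length Genome length in bp.
#' @param gc Target GC fraction (realized GC lands within about 0.5\%).
#' @param skew_amplitude Difference between C and G frequencies within a
#'   half; must satisfy `0 <= skew_amplitude < min(gc, 1 - gc)`.
#' @param n_genes Number of non-overlapping gene intervals to lay out.
#' @param seed Integer seed.
#' @param cazy_families Pool of CAZy family labels sampled for ~10\% of
#'   genes.
#' @return List with `sequence` (character), `genes` (`data.frame`:
#'   `gene_id`, `start`, `end`, `annotated`, `cazy_family`), `ori_true`
#'   and `ter_true` (the constructed switch points, 1-based).
#' @export
simulate_genome <- function(length, gc, skew_amplitude = 0, n_genes = 0L,
                            seed = 1L,
                            cazy_families = c("GH5", "GH13", "GH3", "GT2",
                                              "GT4", "CBM44", "PL1", "CE1")) {
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)", call. = FALSE)
  if (skew_amplitude < 0 || skew_amplitude >= min(gc, 1 - gc))
    stop("skew_amplitude must satisfy 0 <= amplitude < min(gc, 1 - gc), got ",
         skew_amplitude, call. = FALSE)
  length <- as.integer(length)
  half <- length %/% 2L
  pAT <- (1 - gc) / 2
  withr::with_seed(seed, {
    # first half C-rich, second half G-rich
    first <- sample(c("A", "C", "G", "T"), half, replace = TRUE,
                    prob = c(pAT, gc / 2 + skew_amplitude / 2,
                             gc / 2 - skew_amplitude / 2, pAT))
    second <- sample(c("A", "C", "G", "T"), length - half, replace = TRUE,
                     prob = c(pAT, gc / 2 - skew_amplitude / 2,
                              gc / 2 + skew_amplitude / 2, pAT))
    seq <- paste(c(first, second), collapse = "")

    genes <- NULL
    if (n_genes > 0L) {
      slot <- length %/% n_genes
      if (slot < 60L)
        stop("too many genes for the genome length", call. = FALSE)
      glen <- pmin(slot - 10L, round(stats::runif(n_genes, 0.5, 0.95) * slot))
      start <- (seq_len(n_genes) - 1L) * slot + 1L
      genes <- data.frame(
        gene_id = sprintf("gene_%04d", seq_len(n_genes)),
        start = start,
        end = start + glen - 1L,
        annotated = stats::rbinom(n_genes, 1L, 0.6),
        cazy_family = ifelse(stats::runif(n_genes) < 0.1,
                             sample(cazy_families, n_genes, replace = TRUE),
                             ""),
        stringsAsFactors = FALSE
      )
    }
    list(sequence = seq, genes = genes,
         ori_true = half + 1L, ter_true = 1L)
  })
}
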