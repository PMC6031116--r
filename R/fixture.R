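#' Generate a complete synthetic SIP study fixture
#'
#' Writes, to a directory, the full set of input files the analysis
#' pipeline consumes, mirroring the design of a rhizosphere SIP experiment:
#' a labeled "rhizosphere" treatment gradient and an unlabeled "bulk"
#' control gradient over the same soil community; a focal low-GC labeled
#' genome (GC 49.95\%, AFE 0.85) embedded in a higher-GC (0.58-0.70)
#' background that is mostly unlabeled, partly moderately labeled, plus one
#' highly labeled (AFE 1) population so the treatment develops a genuine
#' heavy shoulder; the focal genome's sequence with imposed replication
#' strand bias and its gene table; per-fraction coverage of every genome;
#' and a `truth.json` recording the simulated ground truth (focal AFE and
#' band centre, origin/terminus switch points, genome statistics) for
#' parameter-recovery checks.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param focal_afe True 13C atom-fraction excess of the focal genome.
#' @param focal_length Focal genome length in bp.
#' @param config A [gradient_config()]; its seed is overridden by `seed`.
#' @return Invisibly, a list with `paths` (the written file paths) and
#'   `truth` (the ground-truth record).
#' @export
make_study_fixture <- function(dir, seed = 42L, focal_afe = 0.85,
                               focal_length = 150000L,
                               config = gradient_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)

  treatment_taxa <- sim_taxa(
    taxon_id = c("focal", "hot_bg", "partial_bg", "bg66", "bg62", "bg70"),
    abundance = c(0.05, 0.18, 0.12, 0.40, 0.15, 0.10),
    gc = c(0.4995, 0.60, 0.66, 0.66, 0.62, 0.70),
    afe = c(focal_afe, 1.0, 0.4, 0, 0, 0),
    genome_length = c(focal_length, 2.5e6, 3e6, 4e6, 3.5e6, 5e6)
  )
  control_taxa <- sim_taxa(
    taxon_id = c("hot_bg", "partial_bg", "bg66", "bg62", "bg70"),
    abundance = c(0.15, 0.12, 0.43, 0.17, 0.13),
    gc = c(0.60, 0.66, 0.66, 0.62, 0.70),
    afe = c(0, 0, 0, 0, 0),
    genome_length = c(2.5e6, 3e6, 4e6, 3.5e6, 5e6)
  )

  treat <- simulate_gradient(treatment_taxa, config,
                             sample_id = "rhizosphere", role = "treatment")
  ctrl_config <- config
  ctrl_config$seed <- config$seed + 1L
  ctrl <- simulate_gradient(control_taxa, ctrl_config,
                            sample_id = "bulk", role = "control")

  genome <- simulate_genome(focal_length, gc = 0.4995,
                            skew_amplitude = 0.08, n_genes = 150L,
                            seed = seed)
  stats <- genome_stats(genome$sequence, genome$genes,
                        genome_id = "focal", environment = "synthetic")

  paths <- list(
    treatment = file.path(dir, "treatment.tsv"),
    control = file.path(dir, "control.tsv"),
    coverage = file.path(dir, "coverage_treatment.tsv"),
    genome = file.path(dir, "focal_genome.fasta"),
    genes = file.path(dir, "focal_genes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_profile(treat$profile, paths$treatment)
  write_profile(ctrl$profile, paths$control)
  utils::write.table(treat$coverage, paths$coverage, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(genome$sequence, "focal")),
    paths$genome)
  utils::write.table(genome$genes, paths$genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    focal_id = "focal",
    focal_afe = focal_afe,
    focal_gc = 0.4995,
    focal_band_centre = density_from_enrichment(0.4995, focal_afe,
                                                config$model),
    ori_true = genome$ori_true,
    ter_true = genome$ter_true,
    genome_stats = as.list(as.data.frame(stats)),
    seed = as.integer(seed)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth))
}

#' Read a fixture's ground-truth record
#' @param path Path to a `truth.json` written by [make_study_fixture()].
#' @return Named list of true parameter values.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
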