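#' Validate a pipeline run configuration
#'
#' Collects and validates everything one end-to-end SIP analysis needs:
#' input paths, the isotope model (overridable constants), either explicit
#' bin cutoffs or auto-binning thresholds, skew window/step, the focal
#' genome, and the output directory. The validated configuration is
#' serialized into the output directory for provenance.
#'
#' @param treatment,control Paths to the treatment and control fraction
#'   TSVs.
#' @param coverage Path to the per-fraction coverage TSV.
#' @param focal_genome Path to the focal genome FASTA.
#' @param focal_genes Path to the focal gene table (TSV or GFF3).
#' @param focal_id Genome id of the focal genome in the coverage table and
#'   comparison.
#' @param gc GC fraction of the focal genome, or NULL to compute it from
#'   the sequence.
#' @param scheme A [bin_scheme()] for explicit cutoffs, or NULL to derive
#'   cutoffs with [auto_bin()].
#' @param epsilon,delta [auto_bin()] thresholds (used when `scheme` is
#'   NULL).
#' @param window,step GC-skew window and step in bp.
#' @param reference_stats Path to a genome-statistics TSV used as the
#'   comparison reference set, or NULL to skip the comparison stage when
#'   the focal row is the only one (defaults to the bundled complete
#'   Saccharibacteria table).
#' @param model An [isotope_model()].
#' @param out_dir Output directory.
#' @param seed Integer seed (provenance only; the pipeline itself is
#'   deterministic).
#' @return A validated `run_config` list.
#' @export
run_config <- function(treatment, control, coverage, focal_genome,
                       focal_genes, focal_id = "focal", gc = NULL,
                       scheme = NULL, epsilon = 0.05, delta = 0.02,
                       window = 1000L, step = 10L,
                       reference_stats = system.file(
                         "extdata", "saccharibacteria_genomes.tsv",
                         package = "sipscope"),
                       model = isotope_model(), out_dir = "sipscope_out",
                       seed = 1L) {
  for (p in c(treatment, control)) {
    if (!file.exists(p))
      stop_stage("config", "fraction table not found: ", p)
  }
  if (!is.null(scheme) && !inherits(scheme, "bin_scheme"))
    stop_stage("config", "scheme must be a bin_scheme or NULL")
  if (!is.null(gc)) check_gc(gc)
  structure(
    list(treatment = treatment, control = control, coverage = coverage,
         focal_genome = focal_genome, focal_genes = focal_genes,
         focal_id = focal_id, gc = gc, scheme = scheme,
         epsilon = epsilon, delta = delta,
         window = as.integer(window), step = as.integer(step),
         reference_stats = reference_stats, model = model,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from JSON or YAML
#'
#' Recognized keys mirror the [run_config()] arguments; `isotope_model` may
#' be a mapping of constant overrides, and `scheme` a mapping of
#' `light`/`middle`/`heavy` `[lo, hi]` pairs.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_stage("config", "config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  model <- do.call(isotope_model, as.list(raw$isotope_model))
  scheme <- if (!is.null(raw$scheme))
    bin_scheme(light = unlist(raw$scheme$light),
               middle = unlist(raw$scheme$middle),
               heavy = unlist(raw$scheme$heavy))
  args <- raw[setdiff(names(raw), c("isotope_model", "scheme"))]
  do.call(run_config, c(args, list(model = model, scheme = scheme)))
}

#' Run the full SIP analysis pipeline
#'
#' Executes the stages of a quantitative SIP analysis in workflow order —
#' load gradient profiles, bin fractions (explicit cutoffs when supplied,
#' otherwise treatment-vs-control auto-binning), normalize per-fraction
#' coverage, estimate the focal genome's density centroid and 13C
#' enrichment, compute GC skew with an origin/terminus call and rotate the
#' genome to the predicted origin, and build the comparative
#' genome-statistics table — writing per-stage TSV outputs and a single
#' JSON report into the configured output directory. Progress is logged to
#' stderr with stage-tagged lines; any stage failure aborts with the stage
#' name.
#'
#' @param config A [run_config()] (or path to a JSON/YAML config file).
#' @return The report, invisibly: a named list also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  log_stage("load", "reading gradient profiles")
  treatment <- load_profile(config$treatment, sample_id = "treatment",
                            role = "treatment", model = config$model)
  control <- load_profile(config$control, sample_id = "control",
                          role = "control", model = config$model)

  log_stage("bin", if (is.null(config$scheme))
    sprintf("deriving cutoffs (epsilon = %g, delta = %g)",
            config$epsilon, config$delta)
    else "using explicit cutoffs")
  scheme <- if (is.null(config$scheme))
    auto_bin(treatment, control, config$epsilon, config$delta)
    else config$scheme
  binned <- assign_bins(treatment, scheme)
  write_profile(binned, file.path(config$out_dir, "binned_treatment.tsv"))

  log_stage("enrich", "normalizing coverage and estimating enrichment")
  if (!file.exists(config$coverage))
    stop_stage("enrich", "coverage file not found: ", config$coverage)
  cov <- utils::read.delim(config$coverage, sep = "\t",
                           stringsAsFactors = FALSE)
  cov <- normalize_coverage(cov)
  utils::write.table(cov, file.path(config$out_dir, "coverage_normalized.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  focal_cov <- cov[cov$genome_id == config$focal_id, , drop = FALSE]
  if (!nrow(focal_cov))
    stop_stage("enrich", "focal genome '", config$focal_id,
               "' absent from the coverage table")
  centroid <- genome_density_centroid(focal_cov, treatment)

  log_stage("skew", "GC skew and origin/terminus of the focal genome")
  if (!file.exists(config$focal_genome))
    stop_stage("skew", "focal genome FASTA not found: ", config$focal_genome)
  genome <- read_genome(config$focal_genome)
  gc <- config$gc
  if (is.null(gc)) {
    freq <- Biostrings::letterFrequency(genome, c("G", "C", "A", "T"))
    gc <- sum(freq[c("G", "C")]) / sum(freq)
  }
  afe <- enrichment_from_density(centroid, gc, config$model)
  skew <- gc_skew(genome, window = config$window, step = config$step,
                  circular = TRUE)
  write_skew_profile(skew, file.path(config$out_dir, "skew_profile.tsv"))
  call <- predict_ori_ter(skew)
  rotated <- rotate_to_origin(genome, call$ori_pos)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(as.character(rotated),
                                             config$focal_id)),
    file.path(config$out_dir, "genome_rotated.fasta"))

  log_stage("compare", "comparative genome statistics")
  if (!file.exists(config$focal_genes))
    stop_stage("compare", "focal gene table not found: ", config$focal_genes)
  genes <- read_gene_table(config$focal_genes)
  focal_stats <- genome_stats(genome, genes, genome_id = config$focal_id,
                              environment = "this_study")
  comparison <- NULL
  if (!is.null(config$reference_stats) && nzchar(config$reference_stats)) {
    ref <- load_genome_stats(config$reference_stats)
    rows <- rbind(as.data.frame(focal_stats),
                  ref[ref$genome_id != config$focal_id,
                      names(focal_stats), drop = FALSE])
    comparison <- build_comparison(rows, config$focal_id)
    write_comparison(comparison, file.path(config$out_dir, "comparison.tsv"))
  }

  report <- list(
    scheme = list(light = scheme$light, middle = scheme$middle,
                  heavy = scheme$heavy),
    pooled_mass = as.list(attr(binned, "pooled_mass")),
    focal_coverage_by_bin = as.list(tapply(
      focal_cov$normalized,
      binned$bin[match(focal_cov$fraction_id, binned$fraction_id)],
      sum, default = 0)),
    density_centroid = centroid,
    focal_gc = gc,
    enrichment = list(afe = afe$afe, afe_lower = afe$afe_lower,
                      afe_upper = afe$afe_upper,
                      unlabeled_density = afe$unlabeled_density),
    ori_ter = list(ori_pos = call$ori_pos, ter_pos = call$ter_pos,
                   amplitude = call$amplitude),
    focal_stats = as.list(as.data.frame(focal_stats)),
    diff_from_average = if (!is.null(comparison))
      as.list(comparison$diff_from_average),
    pct_larger_than_largest = if (!is.null(comparison))
      comparison$pct_larger_than_largest,
    seed = config$seed
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done", "report written to ",
            file.path(config$out_dir, "report.json"))
  invisible(report)
}
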