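test_that("simulated genomes hit their GC target and are seed-deterministic", {
  g1 <- simulate_genome(1e5, gc = 0.5, skew_amplitude = 0.1, n_genes = 20,
                        seed = 1)
  gc_real <- sum(strsplit(g1$sequence, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc_real - 0.5), 0.005)
  g2 <- simulate_genome(1e5, gc = 0.5, skew_amplitude = 0.1, n_genes = 20,
                        seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(
    g1$sequence,
    simulate_genome(1e5, 0.5, 0.1, 20, seed = 2)$sequence))
  # gene intervals never overlap
  ord <- order(g1$genes$start)
  expect_true(all(g1$genes$start[ord][-1] > g1$genes$end[ord][-20]))
  expect_error(simulate_genome(1e4, gc = 0.3, skew_amplitude = 0.35),
               "amplitude")
})

test_that("zero skew amplitude leaves no origin signal", {
  g <- simulate_genome(5e4, gc = 0.5, skew_amplitude = 0, seed = 3)
  p <- gc_skew(g$sequence, 1000, 10, circular = TRUE)
  # cumulative drift is pure sampling noise, far below a real bias signal
  biased <- gc_skew(simulate_genome(5e4, 0.5, 0.1, seed = 3)$sequence,
                    1000, 10, circular = TRUE)
  expect_lt(max(p$cumulative) - min(p$cumulative),
            (max(biased$cumulative) - min(biased$cumulative)) / 5)
})

test_that("gradient simulation conserves mass and centres bands", {
  taxa <- sim_taxa("t", 1, gc = 0.4995, afe = 0, genome_length = 1e6)
  sim <- simulate_gradient(taxa, gradient_config(seed = 1))
  # mass conservation up to the truncated tails
  expect_equal(sum(sim$profile$dna_conc), 100 * (1 - sim$truncated[["t"]]),
               tolerance = 1e-6)
  # mass-weighted mean density sits at the band centre
  mwd <- with(sim$profile, sum(density * dna_conc) / sum(dna_conc))
  expect_lt(abs(mwd - gc_to_density(0.4995)), 0.001)
  expect_true(all(sim$coverage$coverage >= 0))
  expect_equal(max(sim$coverage$coverage), 15)  # peak-coverage anchor
  # densities are collected densest-first
  expect_true(all(diff(sim$profile$density) < 0))
})

test_that("a labeled taxon produces a heavy bin containing its band", {
  taxa_t <- sim_taxa(c("bg", "hot"), c(0.8, 0.2), gc = c(0.5, 0.5),
                     afe = c(0, 1), genome_length = c(1e6, 1e6))
  taxa_c <- sim_taxa("bg", 1, gc = 0.5, afe = 0, genome_length = 1e6)
  treat <- simulate_gradient(taxa_t, gradient_config(seed = 42))
  ctrl <- simulate_gradient(taxa_c, gradient_config(seed = 43),
                            role = "control")
  scheme <- auto_bin(treat$profile, ctrl$profile)
  hot_centre <- density_from_enrichment(0.5, 1)
  expect_false(is.null(scheme$heavy))
  expect_true(scheme$heavy[1] <= hot_centre && hot_centre <= scheme$heavy[2])
})

test_that("band centres outside the gradient span warn and truncate", {
  taxa <- sim_taxa("hi_gc", 1, gc = 0.95, afe = 1, genome_length = 1e6)
  expect_warning(sim <- simulate_gradient(taxa, gradient_config(seed = 1)),
                 "outside the gradient span")
  expect_gt(sim$truncated[["hi_gc"]], 0.5)
})

test_that("recovered enrichment degrades monotonically with band spread", {
  err_for_sd <- function(sd) {
    errs <- vapply(1:10, function(seed) {
      taxa <- sim_taxa("t", 1, gc = 0.5, afe = 0.5, genome_length = 1e6)
      sim <- simulate_gradient(taxa, gradient_config(band_sd = sd,
                                                     seed = seed,
                                                     noise_sd = 0.2))
      cen <- genome_density_centroid(sim$coverage, sim$profile)
      abs(enrichment_from_density(cen, 0.5)$afe - 0.5)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0.001, 0.003, 0.006, 0.012, 0.024), err_for_sd,
                 numeric(1))
  # wider bands never improve accuracy (tiny slack for seed noise)
  expect_true(all(diff(errs) > -0.005))
  expect_lt(errs[1], 0.05)
})

test_that("study fixtures are written completely and round-trip", {
  dir <- tempfile()
  fx <- make_study_fixture(dir, seed = 42)
  expect_true(all(file.exists(unlist(fx$paths))))
  truth <- read_truth(fx$paths$truth)
  expect_equal(truth$focal_afe, fx$truth$focal_afe)
  expect_equal(truth$ori_true, fx$truth$ori_true)
  prof <- load_profile(fx$paths$treatment, role = "treatment")
  expect_s3_class(prof, "gradient_profile")
  genes <- read_gene_table(fx$paths$genes)
  expect_equal(nrow(genes), truth$genome_stats$gene_number)
  # negative control: background-only fixture shows no enrichment
  fx0 <- make_study_fixture(tempfile(), seed = 42, focal_afe = 0)
  cov <- read.delim(fx0$paths$coverage)
  prof0 <- load_profile(fx0$paths$treatment, role = "treatment")
  cen <- genome_density_centroid(normalize_coverage(
    cov[cov$genome_id == "focal", ]), prof0)
  expect_equal(enrichment_from_density(cen, 0.4995)$afe, 0, tolerance = 0.02)
})
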