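test_that("genome statistics are computed from sequence and gene table", {
  genes <- data.frame(gene_id = c("a", "b"), start = c(1001, 5001),
                      end = c(2000, 6000), annotated = c(1L, 0L),
                      cazy_family = c("GH5", ""))
  st <- genome_stats(10000, genes, genome_id = "toy")
  expect_equal(st$genome_size, 10000)
  expect_equal(st$gene_number, 2)
  expect_equal(st$unannotated_genes, 1)
  expect_equal(st$total_coding, 2000)
  expect_equal(st$coding_density, 20.0)
  expect_equal(st$average_gene_size, 1000)
  expect_equal(st$cazy_genes, 1)
})

test_that("overlapping genes count coding bases once (union semantics)", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      start = c(1, 1, 500), end = c(1000, 1000, 1500),
                      annotated = 1L,
                      cazy_family = c("GH5", "GH5", "GT2"))
  st <- genome_stats(10000, genes)
  expect_equal(st$total_coding, 1500)  # [1,1000] u [1,1000] u [500,1500]
  expect_equal(st$cazy_genes, 3)
  expect_equal(st$unduplicated_cazy, 2)
  bad <- data.frame(gene_id = "x", start = 9000, end = 10500,
                    annotated = 1L, cazy_family = "")
  expect_error(genome_stats(10000, bad), "out of genome bounds at row 1")
})

test_that("difference from average reproduces the published row", {
  tab <- saccharibacteria_stats()
  cmp <- build_comparison(tab, "Ca_T_rhizospherense")
  d <- round(cmp$diff_from_average, 1)
  expect_equal(d[["genome_size"]], 32.4)
  expect_equal(d[["gene_number"]], 33.2)
  expect_equal(d[["unannotated_genes"]], 39.1)
  expect_equal(d[["average_gene_size"]], -3.7)
  expect_equal(d[["total_coding"]], 30.6)
  expect_equal(d[["cazy_genes"]], 39.9)
  expect_equal(d[["unduplicated_cazy"]], 31.7)
  expect_equal(round(d[["coding_density"]]), -3)
  expect_equal(round(cmp$pct_larger_than_largest), 28)
})

test_that("comparative percentages behave on edge cases", {
  v <- c(a = 200, b = 100)
  expect_equal(pct_larger_than_largest(v, "a"), 50)
  expect_lt(pct_larger_than_largest(v, "b"), 0)  # focal smaller: negative
  same <- c(a = 7, b = 7, c = 7)
  expect_equal(diff_from_average(same, "b"), 0)
  expect_error(diff_from_average(c(a = 0, b = 1), "a"), "zero")
  expect_error(diff_from_average(c(a = 1), "a"), "at least 2")
  expect_error(pct_larger_than_largest(v, "zz"), "not found")
})

test_that("percentages match a brute-force oracle on random tables", {
  oracle_diff <- function(values, focal) {
    s <- 0
    for (v in values) s <- s + v
    (values[[focal]] - s / length(values)) / values[[focal]] * 100
  }
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    v <- setNames(runif(n, 1, 1000), paste0("g", seq_len(n)))
    focal <- sample(names(v), 1)
    expect_equal(diff_from_average(v, focal), oracle_diff(v, focal),
                 tolerance = 1e-12)
    # scaling all values leaves both percentages unchanged
    expect_equal(diff_from_average(v * 3.7, focal),
                 diff_from_average(v, focal), tolerance = 1e-9)
    expect_equal(pct_larger_than_largest(v * 3.7, focal),
                 pct_larger_than_largest(v, focal), tolerance = 1e-9)
  }
})

test_that("comparison tables build, reject duplicates, and write TSV", {
  tab <- saccharibacteria_stats()
  expect_error(build_comparison(rbind(tab, tab[1, ]),
                                "Ca_T_rhizospherense"), "duplicate")
  cmp <- build_comparison(tab, "Ca_T_rhizospherense")
  path <- tempfile(fileext = ".tsv")
  write_comparison(cmp, path)
  out <- read.delim(path)
  expect_equal(nrow(out), nrow(tab) + 1)
  expect_equal(out$genome_id[nrow(out)], "difference_from_average")
  expect_equal(out$genome_size[nrow(out)], 32.4)
  # identical focal and other give an all-zero difference row
  two <- tab[1:2, ]
  two[2, -(1:2)] <- two[1, -(1:2)]
  two$genome_id[2] <- "clone"
  z <- build_comparison(two, "Ca_T_rhizospherense")
  expect_true(all(abs(z$diff_from_average) < 1e-12))
})

test_that("gene tables read from TSV and GFF3 agree", {
  genes <- data.frame(gene_id = c("g1", "g2"), start = c(10, 300),
                      end = c(200, 450), annotated = c(1L, 0L),
                      cazy_family = c("", "GH13"))
  tsv <- tempfile(fileext = ".tsv")
  write.table(genes, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_table(tsv), genes)

  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t10\t200\t.\t+\t.\tID=g1;annotated=1",
    "chr1\ttest\tgene\t300\t450\t.\t+\t.\tID=g2;annotated=0;cazy_family=GH13"
  ), gff)
  got <- read_gene_table(gff)
  expect_equal(got$start, genes$start)
  expect_equal(got$end, genes$end)
  expect_equal(got$annotated, genes$annotated)
  expect_equal(got$cazy_family, genes$cazy_family)
})
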