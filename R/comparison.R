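#' Percent difference of a focal genome from the group average
#'
#' For one numeric column of a genome-statistics table, the focal genome's
#' deviation from the mean of all genomes (focal included), expressed as a
#' percentage of the focal value:
#' \eqn{100 (x_{focal} - \bar{x}) / x_{focal}}. This denominator/mean
#' convention is the one under which the published comparative rows for
#' complete Saccharibacteria genomes reproduce from their printed columns.
#'
#' @param values Named numeric vector, one value per genome (names are
#'   genome ids).
#' @param focal_id Name of the focal genome.
#' @return Percentage (not rounded).
#' @examples
#' sizes <- c(a = 200, b = 100, c = 100)
#' diff_from_average(sizes, "a") # 100 * (200 - 400/3) / 200
#' @export
diff_from_average <- function(values, focal_id) {
  if (length(values) < 2L)
    stop("need at least 2 genomes", call. = FALSE)
  if (!focal_id %in% names(values))
    stop("focal genome '", focal_id, "' not found", call. = FALSE)
  focal <- values[[focal_id]]
  if (focal == 0)
    stop("focal value is zero; percent difference undefined", call. = FALSE)
  100 * (focal - mean(values)) / focal
}

#' Percent by which the focal genome exceeds the largest other genome
#'
#' \eqn{100 (x_{focal} - \max_{others}) / x_{focal}}; negative when the
#' focal genome is smaller than the largest of the others.
#'
#' @inheritParams diff_from_average
#' @return Percentage (not rounded).
#' @export
pct_larger_than_largest <- function(values, focal_id) {
  if (length(values) < 2L)
    stop("need at least 2 genomes", call. = FALSE)
  if (!focal_id %in% names(values))
    stop("focal genome '", focal_id, "' not found", call. = FALSE)
  focal <- values[[focal_id]]
  if (focal == 0)
    stop("focal value is zero; percentage undefined", call. = FALSE)
  100 * (focal - max(values[names(values) != focal_id])) / focal
}

numeric_stat_columns <- c("genome_size", "gene_number", "unannotated_genes",
                          "average_gene_size", "total_coding",
                          "coding_density", "cazy_genes", "unduplicated_cazy")

#' Build a comparative genome-statistics table
#'
#' Combines per-genome statistics rows into a comparison table with a
#' difference-from-average row (every numeric column, via
#' [diff_from_average()]) and the percent by which the focal genome size
#' exceeds the largest other genome ([pct_larger_than_largest()]).
#'
#' @param rows `data.frame` of genome statistics ([genome_stats()] rows or
#'   [load_genome_stats()] output), one genome per row.
#' @param focal_id `genome_id` of the focal genome.
#' @return A `comparison_table`: list with `stats` (the input rows),
#'   `focal_id`, `diff_from_average` (named numeric, unrounded) and
#'   `pct_larger_than_largest`.
#' @export
build_comparison <- function(rows, focal_id) {
  if (nrow(rows) < 2L) stop("need at least 2 genomes", call. = FALSE)
  if (anyDuplicated(rows$genome_id))
    stop("duplicate genome_id: ",
         rows$genome_id[duplicated(rows$genome_id)][1L], call. = FALSE)
  if (!focal_id %in% rows$genome_id)
    stop("focal genome '", focal_id, "' not found", call. = FALSE)
  cols <- intersect(numeric_stat_columns, names(rows))
  diffs <- vapply(cols, function(cl) {
    v <- rows[[cl]]; names(v) <- rows$genome_id
    diff_from_average(v, focal_id)
  }, numeric(1))
  sizes <- rows$genome_size; names(sizes) <- rows$genome_id
  structure(
    list(stats = rows, focal_id = focal_id, diff_from_average = diffs,
         pct_larger_than_largest = pct_larger_than_largest(sizes, focal_id)),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("comparison_table: ", nrow(x$stats), " genomes, focal = ", x$focal_id,
      "\n", sep = "")
  print.data.frame(x$stats)
  cat("difference from average (%):\n")
  print(round(x$diff_from_average, 1))
  cat(sprintf("focal genome is %.0f%% larger than the largest other genome\n",
              x$pct_larger_than_largest))
  invisible(x)
}

#' Write a comparison table to TSV
#'
#' Emits the per-genome rows followed by a `difference_from_average` row
#' with percentages at one decimal, mirroring how such tables are printed.
#'
#' @param x A `comparison_table`.
#' @param path Output path.
#' @export
write_comparison <- function(x, path) {
  tab <- x$stats
  diff_row <- tab[1L, , drop = FALSE]
  diff_row[1L, ] <- NA
  diff_row$genome_id <- "difference_from_average"
  for (cl in names(x$diff_from_average))
    diff_row[[cl]] <- round(x$diff_from_average[[cl]], 1)
  out <- rbind(tab, diff_row)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
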