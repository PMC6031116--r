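#' Read a genome sequence from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that returns the
#' single record of a one-genome FASTA as a `DNAString`.
#'
#' @param path Path to the FASTA file.
#' @return A `DNAString`.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected a single-record FASTA, got ", length(set), " records: ",
         path, call. = FALSE)
  set[[1L]]
}

#' Read a gene table from TSV or GFF3
#'
#' The native format is a tab-separated table with columns `gene_id`,
#' `start`, `end` (1-based inclusive), `annotated` (0/1 functional
#' annotation status) and `cazy_family` (CAZy family string, empty when the
#' gene is not a carbohydrate-active enzyme). GFF3 input (`.gff`/`.gff3`,
#' read through rtracklayer) is mapped onto the same columns, taking
#' `annotated` and `cazy_family` from identically named attributes (a
#' missing `annotated` attribute counts as annotated).
#'
#' @param path Path to the gene table.
#' @return `data.frame` with the five columns above.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 gene tables requires the rtracklayer package",
           call. = FALSE)
    gr <- rtracklayer::import(path)
    mc <- as.data.frame(gr)
    tab <- data.frame(
      gene_id = if ("ID" %in% names(mc)) as.character(mc$ID)
                else paste0("gene_", seq_along(gr)),
      start = mc$start, end = mc$end,
      annotated = if ("annotated" %in% names(mc))
        as.integer(as.character(mc$annotated)) else 1L,
      cazy_family = if ("cazy_family" %in% names(mc))
        as.character(mc$cazy_family) else "",
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    req <- c("gene_id", "start", "end", "annotated")
    miss <- setdiff(req, names(tab))
    if (length(miss))
      stop("gene table is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!"cazy_family" %in% names(tab)) tab$cazy_family <- ""
  }
  tab$cazy_family[is.na(tab$cazy_family)] <- ""
  tab
}

#' Per-genome summary statistics from sequence and gene table
#'
#' Computes the standard comparative-genomics columns for one genome:
#' genome size, gene number, number of genes without a functional
#' annotation, mean gene length, total coding length (union of gene
#' intervals, so overlapping genes are counted once), coding density,
#' number of CAZy (carbohydrate-active enzyme) genes, and the number of
#' distinct CAZy families ("unduplicated" CAZy genes).
#'
#' @param sequence Genome sequence (character, `DNAString`, length-1
#'   `DNAStringSet`) or a bare genome length in bp.
#' @param genes Gene table as returned by [read_gene_table()].
#' @param genome_id Identifier used in comparison tables.
#' @param environment Environment-of-origin label (free text).
#' @return A one-row `data.frame` of class `genome_stats`.
#' @export
genome_stats <- function(sequence, genes, genome_id = "genome",
                         environment = NA_character_) {
  genome_size <- if (is.numeric(sequence) && length(sequence) == 1L)
    as.integer(sequence) else nchar(as_sequence_string(sequence))
  if (!nrow(genes)) stop("empty gene table", call. = FALSE)
  if (any(genes$start < 1L | genes$end > genome_size | genes$start > genes$end)) {
    bad <- which(genes$start < 1L | genes$end > genome_size |
                   genes$start > genes$end)[1L]
    stop("gene interval out of genome bounds at row ", bad, " (",
         genes$start[bad], "-", genes$end[bad], " vs genome size ",
         genome_size, ")", call. = FALSE)
  }
  iv <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
  total_coding <- sum(IRanges::width(iv))
  cazy <- genes$cazy_family
  cazy <- cazy[!is.na(cazy) & nzchar(cazy)]
  out <- data.frame(
    genome_id = genome_id,
    environment = environment,
    genome_size = genome_size,
    gene_number = nrow(genes),
    unannotated_genes = sum(genes$annotated == 0L),
    average_gene_size = mean(genes$end - genes$start + 1),
    total_coding = total_coding,
    coding_density = 100 * total_coding / genome_size,
    cazy_genes = length(cazy),
    unduplicated_cazy = length(unique(cazy)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_stats", "data.frame")
  out
}

#' Load a table of per-genome statistics from TSV
#'
#' Reads a TSV whose columns match the [genome_stats()] output (one genome
#' per row), e.g. a table of published genome statistics used as the
#' reference set in a comparison.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of genome statistics.
#' @export
load_genome_stats <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("genome_id", "genome_size")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("genome stats table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$genome_id))
    stop("duplicate genome_id in stats table: ",
         tab$genome_id[duplicated(tab$genome_id)][1L], call. = FALSE)
  tab
}

#' Published complete Saccharibacteria genome statistics
#'
#' The bundled reference table of genome statistics for the complete,
#' closed Saccharibacteria (TM7) genomes: the rhizosphere genome
#' *Candidatus* Teamsevenus rhizospherense and the six previously published
#' complete genomes from wastewater, aquifer and human-mouth environments.
#'
#' @return `data.frame` with the [genome_stats()] columns.
#' @export
saccharibacteria_stats <- function() {
  load_genome_stats(system.file("extdata", "saccharibacteria_genomes.tsv",
                                package = "sipscope", mustWork = TRUE))
}
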