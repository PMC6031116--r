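#!/usr/bin/env Rscript
# Stage 4: comparative genome statistics.
#
# Builds the comparison table for the published complete Saccharibacteria
# genomes, with the rhizosphere genome as focal: per-genome statistics, the
# difference-from-average row, and the percentage by which the focal
# genome exceeds the largest other complete genome.

suppressPackageStartupMessages(library(sipscope))

tab <- saccharibacteria_stats()
cmp <- build_comparison(tab, "Ca_T_rhizospherense")
print(cmp)
write_comparison(cmp, "results/comparison_table.tsv")

# the same machinery applied to the synthetic focal genome's own stats
fixture <- "results/fixture"
genome <- read_genome(file.path(fixture, "focal_genome.fasta"))
genes <- read_gene_table(file.path(fixture, "focal_genes.tsv"))
st <- genome_stats(genome, genes, genome_id = "synthetic_focal",
                   environment = "synthetic")
write.table(st, "results/synthetic_focal_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("synthetic focal genome: ", st$genome_size, " bp, ",
        st$gene_number, " genes, coding density ",
        round(st$coding_density, 1), "%")
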