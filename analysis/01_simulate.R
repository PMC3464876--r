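#!/usr/bin/env Rscript
# Build the synthetic study world: a mixed-GC genome with planted CpG
# islands, an accessibility landscape with expression-coupled promoters, and
# nuclease-digestion tag libraries for three enzymes (the G/C-preferring
# Benzonase and Cyanase, and the T-preferring DNase I) plus a 4x-lower-depth
# Benzonase library for the concentration-robustness comparison.

suppressPackageStartupMessages(library(tachseq))
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

genome <- generate_genome(n_contigs = 2, contig_len = 5e6,
                          gc_levels = c(0.3, 0.5, 0.7), n_cpg_islands = 60,
                          seed = seed)
write_fasta(genome, file.path(outdir, "genome.fa"))
write.table(attr(genome, "cpg_islands"),
            file.path(outdir, "islands_planted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("genome: %d contigs, %.1f Mb nuclear + chrM; %d planted CpG islands\n",
            length(genome) - 1, 1e-6 * sum(genome_lengths(genome)[-length(genome)]),
            nrow(attr(genome, "cpg_islands"))))

sim <- generate_landscape(genome, n_regions = 300,
                          intensity_law = list(meanlog = log(3), sdlog = 0.7),
                          promoter_fraction = 0.5, expression_coupling = 2,
                          seed = seed + 1L)
write.table(sim$landscape$regions, file.path(outdir, "regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_table(sim$genes, file.path(outdir, "genes.tsv"))
write_expression(sim$expression, file.path(outdir, "expression.tsv"))
cat(sprintf("landscape: %d regions, intensity median %.1fx baseline; %d genes (%d expressed)\n",
            nrow(sim$landscape$regions),
            median(sim$landscape$regions$intensity),
            length(unique(sim$genes$gene_id)),
            sum(sim$expression$transcripts_per_cell > 0)))

libs <- list(benzonase = c("benzonase", 3e5),
             cyanase = c("cyanase", 3e5),
             dnase1 = c("dnase1", 3e5),
             benzonase_lowdepth = c("benzonase", 75000))
for (i in seq_along(libs)) {
  nm <- names(libs)[i]
  lib <- simulate_digestion(genome, sim$landscape,
                            preset_bias(libs[[i]][1]),
                            n_fragments = as.numeric(libs[[i]][2]),
                            mito_fraction = 0.05, seed = seed + 10L + i,
                            label = nm)
  write_tags_bed(lib, file.path(outdir, sprintf("tags_%s.bed", nm)))
  cat(sprintf("library %-19s %7d tags (%.1f%% chrM)\n", nm,
              library_size(lib), 100 * mito_fraction(lib)))
}
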