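#!/usr/bin/env Rscript
# Accessibility at transcription start sites versus gene expression:
# feature classification of hotspots, TSS occupancy by expression bin, and
# aggregated/ranked tag-density profiles around TSSs.

suppressPackageStartupMessages({
  library(tachseq)
  library(ggplot2)
})
outdir <- "results/analysis"
gl <- genome_lengths(read_fasta(file.path(outdir, "genome.fa")))
genes <- read_gene_table(file.path(outdir, "genes.tsv"))
expr <- read_expression(file.path(outdir, "expression.tsv"))
lib <- read_tags_bed(file.path(outdir, "tags_benzonase.bed"), gl,
                     "benzonase")
hs <- read_hotspots_bed(file.path(outdir, "hotspots_benzonase.bed"),
                        "benzonase")

fd <- feature_distribution(hs, genes)
write.table(fd, file.path(outdir, "feature_distribution_benzonase.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("hotspot feature distribution:\n")
for (i in seq_len(nrow(fd))) {
  cat(sprintf("  %-10s %4d (%.1f%%)\n", fd$category[i], fd$count[i],
              100 * fd$fraction[i]))
}

binning <- bin_expression(expr, "log2")
occ <- tss_occupancy(genes, list(hs), binning)
write.table(occ, file.path(outdir, "tss_occupancy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("TSS hotspot occupancy by expression bin (nd -> high):\n")
cat(sprintf("  %s\n", paste(sprintf("%s:%.0f%%", occ$bin,
                                    100 * occ$occupancy), collapse = " ")))

# aggregated profiles for top-decile vs undetected genes
dec <- bin_expression(expr, "decile")
genes1 <- genes[!duplicated(genes$gene_id), ]
top_ids <- dec$gene_id[dec$bin == "decile1"]
nd_ids <- expr$gene_id[expr$transcripts_per_cell == 0]
prof_top <- aggregate_density(genes1[genes1$gene_id %in% top_ids, ], lib,
                              flank = 3000, bin_width = 50, "tss")
prof_nd <- aggregate_density(genes1[genes1$gene_id %in% nd_ids, ], lib,
                             flank = 3000, bin_width = 50, "tss")
profs <- rbind(data.frame(group = "top decile", prof_top),
               data.frame(group = "not detected", prof_nd))
write.table(profs, file.path(outdir, "tss_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean TSS density (tags/bp/million): top decile %.3f, nd %.3f\n",
            mean(prof_top$density), mean(prof_nd$density)))

p <- ggplot(profs, aes(offset, density, colour = group)) +
  geom_line() +
  labs(x = "offset from TSS (bp)", y = "tags / bp / million") + theme_bw()
ggsave(file.path(outdir, "tss_profiles.png"), p, width = 5.5, height = 3.5,
       dpi = 150)

# heatmap matrix, genes ranked by expression
ord <- order(-expr$transcripts_per_cell, expr$gene_id)
ranked <- genes1[match(expr$gene_id[ord], genes1$gene_id), ]
ranked <- ranked[!is.na(ranked$gene_id), ]
m <- density_heatmap_matrix(ranked, lib, flank = 3000, bin_width = 100,
                            anchor_mode = "tss")
write.table(round(m, 4), file.path(outdir, "tss_heatmap_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("heatmap matrix: %d genes x %d bins\n", nrow(m), ncol(m)))
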