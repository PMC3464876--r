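#!/usr/bin/env Rscript
# Enzyme sequence bias: 5' cut-site base frequencies, GC content of shared
# vs enzyme-unique hotspots, and CpG island overlap by hotspot class.

suppressPackageStartupMessages({
  library(tachseq)
  library(ggplot2)
})
outdir <- "results/analysis"
genome <- read_fasta(file.path(outdir, "genome.fa"))
gl <- genome_lengths(genome)

profiles <- list()
for (enz in c("benzonase", "dnase1")) {
  lib <- read_tags_bed(file.path(outdir, sprintf("tags_%s.bed", enz)), gl,
                       enz)
  prof <- cut_site_base_frequency(lib, genome, k = 10)
  df <- data.frame(offset = prof$offsets, t(prof$freq))
  write.table(df, file.path(outdir, sprintf("base_frequency_%s.tsv", enz)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: modal 5' base %s (%.3f)\n", enz,
              rownames(prof$freq)[which.max(prof$freq[, "0"])],
              max(prof$freq[, "0"])))
  long <- do.call(rbind, lapply(rownames(prof$freq), function(b) {
    data.frame(enzyme = enz, offset = prof$offsets, base = b,
               freq = prof$freq[b, ])
  }))
  profiles[[enz]] <- long
}
p <- ggplot(do.call(rbind, profiles), aes(offset, freq, colour = base)) +
  geom_line() + facet_wrap(~enzyme) +
  labs(x = "offset from cut site (bp)", y = "base frequency") + theme_bw()
ggsave(file.path(outdir, "base_frequency.png"), p, width = 7, height = 3.2,
       dpi = 150)

# GC content and CpG islands by hotspot class
sets <- lapply(setNames(c("benzonase", "dnase1"), c("benzonase", "dnase1")),
               function(enz) read_hotspots_bed(
                 file.path(outdir, sprintf("hotspots_%s.bed", enz)), enz))
um <- union_merge(sets)
klass <- ifelse(um$benzonase & um$dnase1, "common",
                ifelse(um$benzonase, "benzonase_unique", "dnase1_unique"))
gc <- gc_content(um, genome)
islands <- find_cpg_islands(genome)
write.table(islands, file.path(outdir, "cpg_islands_called.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tab <- do.call(rbind, lapply(unique(klass), function(k) {
  data.frame(class = k, n = sum(klass == k),
             median_gc = median(gc[klass == k]),
             cpg_island_fraction = cpg_overlap_fraction(um[klass == k, ],
                                                        islands))
}))
write.table(tab, file.path(outdir, "hotspot_class_gc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(tab))) {
  cat(sprintf("%-18s n=%4d  median GC %.1f%%  CpG-island overlap %.1f%%\n",
              tab$class[i], tab$n[i], 100 * tab$median_gc[i],
              100 * tab$cpg_island_fraction[i]))
}

# positional GC around hotspot classes
gp <- do.call(rbind, lapply(unique(klass), function(k) {
  prof <- gc_profile_around(um[klass == k, ], genome, flank = 2000,
                            bin_width = 10)
  data.frame(class = k, prof)
}))
write.table(gp, file.path(outdir, "gc_profile_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
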