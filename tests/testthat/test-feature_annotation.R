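toy_genes <- function() {
  g <- data.frame(
    gene_id = c("gA", "gB"),
    contig = "c1",
    strand = c("+", "-"),
    tss = c(10000L, 40000L),
    tts = c(20000L, 30000L),
    exons = c("10000-10500,15000-15500,19500-20001",
              "30000-30400,39600-40001"),
    stringsAsFactors = FALSE
  )
  class(g) <- c("gene_models", "data.frame")
  g
}

hs_at <- function(mids) {
  data.frame(contig = rep("c1", length(mids)), start = as.integer(mids - 50),
             end = as.integer(mids + 50))
}

test_that("midpoint classification follows the priority rule", {
  genes <- toy_genes()
  # 1 kb upstream of the + TSS -> promoter
  expect_equal(as.character(classify_hotspots(hs_at(9000), genes)),
               "promoter")
  # upstream of the - strand TSS is to the right
  expect_equal(as.character(classify_hotspots(hs_at(41000), genes)),
               "promoter")
  expect_equal(as.character(classify_hotspots(hs_at(10200), genes)), "exon")
  expect_equal(as.character(classify_hotspots(hs_at(12000), genes)),
               "intron")
  # 2 kb past the + TTS -> downstream; past the - TTS is to the left
  expect_equal(as.character(classify_hotspots(hs_at(21000), genes)),
               "downstream")
  expect_equal(as.character(classify_hotspots(hs_at(29000), genes)),
               "downstream")
  expect_equal(as.character(classify_hotspots(hs_at(200000), genes)),
               "distal")

  # exon of one gene beats intron of an overlapping gene
  g2 <- rbind(genes, data.frame(gene_id = "gC", contig = "c1", strand = "+",
                                tss = 9000L, tts = 18000L, exons = "9000-9100"))
  class(g2) <- c("gene_models", "data.frame")
  expect_equal(as.character(classify_hotspots(hs_at(15200), g2)), "exon")
})

test_that("feature distributions are total and sum to one", {
  genes <- toy_genes()
  fd0 <- feature_distribution(hs_at(numeric(0)), genes)
  expect_true(all(fd0$count == 0))

  hs <- hs_at(c(9000, 10200, 12000, 21000, 200000, 9500))
  fd <- feature_distribution(hs, genes)
  expect_equal(sum(fd$count), nrow(hs))
  expect_equal(sum(fd$fraction), 1)
  expect_equal(fd$count[fd$category == "promoter"], 2L)
  # matches per-hotspot classification
  expect_equal(fd$count,
               as.integer(table(classify_hotspots(hs, genes))[fd$category]))
})

test_that("expression binning assigns nd, log2 bins and deciles", {
  expr <- data.frame(gene_id = sprintf("g%02d", 1:6),
                     transcripts_per_cell = c(0, 0.3, 1.5, 16, 40, 0.9))
  b <- bin_expression(expr, "log2")
  expect_equal(as.character(b$bin[1]), "nd")
  # log2(16) = 4: the bin whose upper boundary is 4
  expect_equal(as.character(b$bin[4]), "bin6")
  expect_equal(as.character(b$bin[5]), "bin8")   # log2(40) ~ 5.3: open top bin
  expect_equal(as.character(b$bin[2]), "bin1")   # log2(0.3) ~ -1.7: bottom bin
  expect_true(all(!is.na(b$bin)))
  expect_error(bin_expression(data.frame(gene_id = "g", transcripts_per_cell = -1)),
               "negative")

  set.seed(9)
  expr20 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       transcripts_per_cell = c(runif(15, 0, 50), rep(0, 5)))
  d <- bin_expression(expr20, "decile")
  # brute-force ranking: descending expression, ties by gene id, 2 per decile
  ord <- order(-expr20$transcripts_per_cell, expr20$gene_id)
  expected <- integer(20)
  expected[ord] <- rep(1:10, each = 2)
  expect_equal(as.character(d$bin), paste0("decile", expected))
})

test_that("TSS occupancy scores genes by their best TSS", {
  genes <- toy_genes()
  expr <- data.frame(gene_id = c("gA", "gB"),
                     transcripts_per_cell = c(8, 0))
  binning <- bin_expression(expr, "log2")
  none <- hotspot_set(data.frame(contig = character(), start = integer(),
                                 end = integer(), tag_count = integer(),
                                 density = numeric(), z = numeric()))
  occ0 <- tss_occupancy(genes, list(none), binning)
  expect_true(all(occ0$occupancy[occ0$n_genes > 0] == 0))

  # gene with two TSSs, one inside a hotspot -> occupied
  g2 <- rbind(genes, data.frame(gene_id = "gA", contig = "c1", strand = "+",
                                tss = 12000L, tts = 20000L, exons = "12000-12100"))
  class(g2) <- c("gene_models", "data.frame")
  hs <- hotspot_set(data.frame(contig = "c1", start = 11950L, end = 12100L,
                               tag_count = 10L, density = 5, z = 6))
  occ <- tss_occupancy(g2, list(hs), binning)
  expect_equal(occ$occupancy[occ$bin == "bin5"], 1)  # gA: t = 8 -> (2,3] = bin5
  expect_equal(occ$occupancy[occ$bin == "nd"], 0)
})

test_that("aggregation profiles bin cut sites around anchors", {
  anchors <- data.frame(contig = "c1", start = 990L, end = 1010L)
  lib <- tag_library(data.frame(contig = "c1", start = 1000L, end = 1036L,
                                strand = "+"))
  prof <- aggregate_density(anchors, lib, flank = 200, bin_width = 50)
  hit <- prof$density > 0
  expect_equal(sum(hit), 1)
  expect_equal(prof$offset[hit], 25)  # cut at offset 0 lands in bin [0, 50)
  expect_error(aggregate_density(anchors[0, ], lib, 200, 50), "no anchors")

  # mirror-image placement around the anchor gives a symmetric profile
  offs <- c(-180L, -120L, -60L, -10L, 9L, 59L, 119L, 179L)
  tags <- data.frame(contig = "c1", start = 1000L + offs,
                     end = 1000L + offs + 36L, strand = "+")
  prof2 <- aggregate_density(anchors, tag_library(tags), flank = 200,
                             bin_width = 20)
  expect_equal(prof2$density, rev(prof2$density))

  # anchor order invariance
  a2 <- data.frame(contig = "c1", start = c(990L, 2990L), end = c(1010L, 3010L))
  p_a <- aggregate_density(a2, tag_library(tags), flank = 100, bin_width = 20)
  p_b <- aggregate_density(a2[2:1, ], tag_library(tags), flank = 100,
                           bin_width = 20)
  expect_equal(p_a$density, p_b$density)
})

test_that("TSS-oriented profiles flip with strand", {
  genes <- data.frame(gene_id = c("p", "m"), contig = "c1",
                      strand = c("+", "-"), tss = c(1000L, 5000L),
                      tts = c(3000L, 4000L), exons = "")
  # one cut 100 bp 3' of each TSS in gene orientation
  lib <- tag_library(data.frame(contig = "c1", start = c(1100L, 4864L),
                                end = c(1136L, 4900L), strand = c("+", "-")))
  m <- density_heatmap_matrix(genes, lib, flank = 200, bin_width = 50,
                              anchor_mode = "tss")
  # cut for the - tag is its end coordinate 4900: offset 5000 - 4900 = 100
  expect_equal(which(m[1, ] > 0), which(m[2, ] > 0))
  expect_equal(as.numeric(colnames(m)[which(m[1, ] > 0)]), 125)
})

test_that("heatmap rows conserve tag counts and average to the profile", {
  sw <- small_world()
  genes <- sw$sim$genes[1:40, ]
  m <- density_heatmap_matrix(genes, sw$lib, flank = 1000, bin_width = 50,
                              anchor_mode = "tss")
  prof <- aggregate_density(genes, sw$lib, flank = 1000, bin_width = 50,
                            anchor_mode = "tss")
  expect_equal(colMeans(m), setNames(prof$density, colnames(m)))

  # conservation: rows times bin width times library millions = cut counts
  counts <- rowSums(m) * 50 * (library_size(sw$lib) / 1e6)
  manual <- vapply(seq_len(nrow(genes)), function(i) {
    t <- sw$lib$tags
    sum(t$contig == genes$contig[i] &
          t$cut >= genes$tss[i] - 1000 + (genes$strand[i] == "-") &
          t$cut < genes$tss[i] + 1000 + (genes$strand[i] == "-"))
  }, numeric(1))
  expect_equal(counts, manual)

  empty_lib <- tag_library(data.frame(contig = "chr1", start = 1L, end = 37L,
                                      strand = "+"))
  m0 <- density_heatmap_matrix(data.frame(contig = "chrM", start = 100L,
                                          end = 200L),
                               empty_lib, flank = 100, bin_width = 50)
  expect_true(all(m0 == 0))
})
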