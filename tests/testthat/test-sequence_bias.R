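toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("cut-site base frequencies respect the strand convention", {
  g <- toy_genome(c(c1 = "AAAAGTTTTTTTTTTTTTTT"))
  # + tag cutting at position 4, whose base is G
  plus <- tag_library(data.frame(contig = "c1", start = 4L, end = 10L,
                                 strand = "+"))
  p <- cut_site_base_frequency(plus, g, k = 2)
  expect_equal(unname(p$freq["G", "0"]), 1.0)
  expect_equal(unname(p$freq["A", "-1"]), 1.0)  # upstream of the cut: A
  expect_equal(unname(p$freq["T", "1"]), 1.0)

  # - tag whose cut coordinate is 5: first sequenced base is the complement
  # of the plus-strand base at position 4 (A) -> T
  g2 <- toy_genome(c(c1 = "GGGGACCCCCCCCCCCCCCC"))
  minus <- tag_library(data.frame(contig = "c1", start = 1L, end = 5L,
                                  strand = "-"))
  m <- cut_site_base_frequency(minus, g2, k = 2)
  expect_equal(unname(m$freq["T", "0"]), 1.0)
  # offset -1 (upstream on the - strand) is the complement of position 5 (C)
  expect_equal(unname(m$freq["G", "-1"]), 1.0)
})

test_that("base frequencies match brute-force character counting", {
  set.seed(33)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  g <- toy_genome(c(c1 = seq))
  tags <- data.frame(contig = "c1",
                     start = sample(5:350, 20),
                     strand = sample(c("+", "-"), 20, replace = TRUE))
  tags$end <- tags$start + 30L
  lib <- tag_library(tags)
  prof <- cut_site_base_frequency(lib, g, k = 6)
  orc <- oracle_base_freq(lib$tags, seq, 6)
  freq_orc <- sweep(orc, 2, colSums(orc), "/")
  expect_equal(unname(prof$freq), unname(freq_orc), tolerance = 1e-12)
  expect_equal(prof$n_tags, 20)
})

test_that("offsets beyond the contig edge drop out of the denominator", {
  g <- toy_genome(c(c1 = "GGGGGGGGGG"))
  lib <- tag_library(data.frame(contig = "c1", start = 1L, end = 8L,
                                strand = "+"))
  p <- cut_site_base_frequency(lib, g, k = 4)
  # offsets -4..-2 reach before the contig: no observations
  expect_true(all(is.na(p$freq[, c("-4", "-3", "-2")])))
  expect_equal(unname(p$freq["G", "0"]), 1.0)
})

test_that("GC content counts only unambiguous bases", {
  g <- toy_genome(c(c1 = "GGCCATATNNGC"))
  iv <- data.frame(contig = "c1", start = c(0L, 4L, 8L),
                   end = c(4L, 8L, 12L))
  expect_equal(gc_content(iv, g), c(1, 0, 1))  # NN excluded from the last

  set.seed(4)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  g2 <- toy_genome(c(c1 = seq))
  chars <- strsplit(seq, "")[[1]]
  expect_equal(gc_content(data.frame(contig = "c1", start = 0L, end = 1000L),
                          g2),
               mean(chars %in% c("G", "C")))
})

test_that("positional GC profiles reproduce constructed composition", {
  g <- toy_genome(c(c1 = strrep("G", 400)))
  anchors <- data.frame(contig = "c1", start = 190L, end = 210L)
  prof <- gc_profile_around(anchors, g, flank = 100, bin_width = 10)
  expect_true(all(prof$gc == 1))
  expect_equal(nrow(prof), 20)

  # step change at the anchor midpoint: A's left, G's right
  g2 <- toy_genome(c(c1 = paste0(strrep("A", 200), strrep("G", 200))))
  prof2 <- gc_profile_around(data.frame(contig = "c1", start = 195L,
                                        end = 205L),
                             g2, flank = 100, bin_width = 10)
  expect_true(all(prof2$gc[prof2$offset < 0] == 0))
  expect_true(all(prof2$gc[prof2$offset > 0] == 1))

  # order invariance over multiple anchors
  a3 <- data.frame(contig = "c1", start = c(150L, 250L, 200L),
                   end = c(170L, 270L, 220L))
  p_a <- gc_profile_around(a3, g2, flank = 50, bin_width = 10)
  p_b <- gc_profile_around(a3[c(3, 1, 2), ], g2, flank = 50, bin_width = 10)
  expect_equal(p_a, p_b)
})

test_that("CpG island calling matches the sliding-window definition", {
  cg300 <- strrep("CG", 150)
  g <- toy_genome(c(c1 = paste0(strrep("A", 500), cg300, strrep("T", 500))))
  isl <- find_cpg_islands(g)
  expect_equal(nrow(isl), 1)
  # the called island covers the repeat (window smearing may extend it by
  # up to one window length on each side)
  expect_lte(isl$start, 500)
  expect_gte(isl$end, 800)
  orc <- oracle_cpg(as.character(g[["c1"]]))
  expect_equal(isl$start, orc$start)
  expect_equal(isl$end, orc$end)

  expect_equal(nrow(find_cpg_islands(toy_genome(c(c1 = strrep("A", 1000))))),
               0)

  set.seed(55)
  for (rep in 1:3) {
    gc <- runif(1, 0.4, 0.7)
    seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                 collapse = "")
    called <- find_cpg_islands(toy_genome(c(c1 = seq)))
    orc <- oracle_cpg(seq)
    expect_equal(called$start, orc$start)
    expect_equal(called$end, orc$end)
  }
})

test_that("CpG overlap fraction is a plain interval share", {
  hs <- data.frame(contig = "c1", start = c(0L, 100L, 200L),
                   end = c(50L, 150L, 250L))
  none <- data.frame(contig = character(0), start = integer(0),
                     end = integer(0))
  expect_equal(cpg_overlap_fraction(hs, none), 0)
  inside <- data.frame(contig = "c1", start = 0L, end = 300L)
  expect_equal(cpg_overlap_fraction(hs, inside), 1)
  one <- data.frame(contig = "c1", start = 120L, end = 130L)
  expect_equal(cpg_overlap_fraction(hs, one),
               mean(overlaps_any_df(hs, one)))
})
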