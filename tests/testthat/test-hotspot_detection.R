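test_that("window z follows the binomial local-background formula", {
  # window [99900, 100150) on a 200250 bp contig: background clipped to
  # [25, 200025), effective length 200000, p = 250/200000 = 0.00125;
  # 100 tags inside the window, 100 elsewhere in the background
  tags <- data.frame(contig = "c1",
                     start = c(rep(99950L, 100), rep(1000L, 100)),
                     end = c(rep(99986L, 100), rep(1036L, 100)),
                     strand = "+")
  lib <- tag_library(tags)
  sc <- scan_zscores(lib, c(c1 = 200250), small_window = 250,
                     background_window = 200000, step = 50)
  w <- sc[sc$start == 99900, ]
  expect_equal(w$n, 100)
  expect_equal(w$N, 200)
  expect_equal(w$p, 0.00125)
  expect_equal(w$z, (100 - 200 * 0.00125) /
                 sqrt(200 * 0.00125 * (1 - 0.00125)), tolerance = 1e-12)
  expect_equal(round(w$z, 1), 199.6)

  expect_error(scan_zscores(tag_library(tags[0, ]), c(c1 = 1000)), "no tags")
})

test_that("windows with an empty background are skipped", {
  # all tags beyond the reach of the first windows' backgrounds
  tags <- data.frame(contig = "c1", start = 90000L, end = 90036L,
                     strand = "+")
  sc <- scan_zscores(tag_library(tags), c(c1 = 100000),
                     small_window = 250, background_window = 2000, step = 250)
  expect_false(any(sc$start < 88000))
  expect_true(any(sc$start >= 89000))
})

test_that("scan z-scores match the brute-force oracle on small instances", {
  set.seed(5)
  for (i in 1:5) {
    L <- sample(2000:10000, 1)
    n <- sample(20:500, 1)
    cuts <- sort(sample(0:(L - 1), n, replace = TRUE))
    lib <- tag_library(data.frame(contig = "c1", start = pmin(cuts, L - 10),
                                  end = pmin(cuts, L - 10) + 10,
                                  strand = "+"))
    sc <- scan_zscores(lib, c(c1 = L), small_window = 100,
                       background_window = 2000, step = 50)
    orc <- oracle_scan(cuts, L, 100, 2000, 50)
    expect_equal(sc$start, orc$start)
    expect_equal(sc$n, orc$n)
    expect_equal(sc$N, orc$N)
    expect_equal(sc$z, orc$z, tolerance = 1e-12)
  }
})

test_that("a planted cluster over uniform background yields one hotspot", {
  bg <- uniform_library(1000, c(c1 = 1e6), seed = 8)
  planted <- data.frame(contig = "c1",
                        start = as.integer(seq(40000, 40299, length.out = 500)),
                        end = as.integer(seq(40000, 40299, length.out = 500)) + 36L,
                        strand = "+")
  lib <- tag_library(rbind(bg$tags[, 1:4], planted))
  hs <- call_hotspots(lib, c(c1 = 1e6), seed = 9)
  expect_equal(nrow(hs), 1)
  expect_lte(hs$start, 40000)
  expect_gte(hs$end, 40299)
  expect_gte(hs$tag_count, 500)
})

test_that("duplicating every tag leaves hotspot intervals unchanged", {
  bg <- uniform_library(1000, c(c1 = 1e6), seed = 8)
  planted <- data.frame(contig = "c1",
                        start = as.integer(seq(40000, 40299, length.out = 500)),
                        end = as.integer(seq(40000, 40299, length.out = 500)) + 36L,
                        strand = "+")
  tags <- rbind(bg$tags[, 1:4], planted)
  # duplicating every record doubles n and N in every window, scaling each
  # z by exactly sqrt(2); at the correspondingly scaled threshold the
  # passing windows, and hence the called intervals, are identical
  thr <- 6
  hs1 <- call_hotspots(tag_library(tags), c(c1 = 1e6),
                       hotspot_params(z_threshold = thr))
  doubled <- tags[rep(seq_len(nrow(tags)), each = 2), ]
  hs2 <- call_hotspots(tag_library(doubled), c(c1 = 1e6),
                       hotspot_params(z_threshold = thr * sqrt(2)))
  expect_equal(hs2$start, hs1$start)
  expect_equal(hs2$end, hs1$end)
  expect_equal(hs2$tag_count, 2L * hs1$tag_count)
  # density is library-size normalized, so doubling cancels
  expect_equal(hs2$density, hs1$density)
})

test_that("called hotspots match the brute-force caller at a fixed threshold", {
  set.seed(21)
  for (i in 1:5) {
    L <- sample(5000:10000, 1)
    n <- sample(100:500, 1)
    # clustered + uniform mixture so some windows pass
    centers <- sample(0:(L - 1), 3)
    cuts <- c(sample(0:(L - 1), n %/% 2, replace = TRUE),
              unlist(lapply(centers, function(cc) {
                pmin(pmax(cc + sample(-40:40, n %/% 6, replace = TRUE), 0), L - 1)
              })))
    lib <- tag_library(data.frame(contig = "c1",
                                  start = pmin(cuts, L - 10),
                                  end = pmin(cuts, L - 10) + 10,
                                  strand = "+"))
    p <- hotspot_params(small_window = 100, background_window = 2000,
                        step = 50, z_threshold = 3, mode_filter = FALSE)
    hs <- call_hotspots(lib, c(c1 = L), p)
    orc <- oracle_hotspots(sort(cuts), L, 100, 2000, 50, 3)
    expect_equal(hs$start, orc$start)
    expect_equal(hs$end, orc$end)
    expect_equal(hs$tag_count, orc$tag_count)
    expect_equal(hs$z, orc$z, tolerance = 1e-12)
  }
})

test_that("FDR-0 threshold is deterministic, sound and tightens with depth", {
  gl <- c(c1 = 1e6)
  t1 <- estimate_fdr0_threshold(1e4, gl, hotspot_params(n_randomizations = 5),
                                seed = 3)
  t2 <- estimate_fdr0_threshold(1e4, gl, hotspot_params(n_randomizations = 5),
                                seed = 3)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_gt(as.numeric(t1), attr(t1, "max_random_z"))

  # the z statistic is right-skewed at low per-window counts, so the
  # maximal standardized score over random placements shrinks toward the
  # Gaussian extreme-value level as depth grows: the threshold tightens
  sizes <- c(1e4, 4e4, 1.6e5)
  means <- vapply(sizes, function(s) {
    mean(vapply(1:10, function(r) {
      as.numeric(estimate_fdr0_threshold(
        s, gl, hotspot_params(n_randomizations = 5), seed = 100 + r))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the density mode filter drops the sub-modal shoulder", {
  mk <- function(d) {
    hotspot_set(data.frame(contig = "c1",
                           start = seq(0, by = 1000, length.out = length(d)),
                           end = seq(500, by = 1000, length.out = length(d)),
                           tag_count = 10L, density = d,
                           z = 5))
  }
  # bimodal toy: mode at 10, the three density-1 hotspots removed
  f <- apply_mode_threshold(mk(c(1, 1, 1, 10, 10, 10, 10)))
  expect_equal(nrow(f), 4)
  expect_true(all(f$density == 10))
  expect_equal(attr(f, "params")$mode_cutoff, 10)

  # all densities equal: single bin, nothing removed
  f2 <- apply_mode_threshold(mk(rep(3.7, 5)))
  expect_equal(nrow(f2), 5)

  # single hotspot returned unchanged
  f3 <- apply_mode_threshold(mk(0.01))
  expect_equal(nrow(f3), 1)

  # filter contract: output a subset with identical intervals
  set.seed(2)
  h <- mk(10^runif(40, -1, 2))
  fh <- apply_mode_threshold(h)
  expect_true(all(paste(fh$start, fh$end) %in% paste(h$start, h$end)))
})

test_that("mitochondrial tags are counted and excluded from calling", {
  tags <- data.frame(contig = c(rep("c1", 45), rep("chrM", 5)),
                     start = 10L, end = 46L, strand = "+")
  lib <- tag_library(tags)
  expect_equal(mito_fraction(lib), 0.1)
  expect_equal(mito_fraction(tag_library(tags[1:3, ])), 0)

  sw <- small_world()
  hs <- call_hotspots(sw$lib, sw$gl, seed = 1)
  expect_false(any(hs$contig == "chrM"))
  expect_equal(attr(hs, "params")$mito_fraction, mito_fraction(sw$lib))
})
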