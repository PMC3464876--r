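# Hotspot calling: a binomial local-background scan statistic, an empirical
# FDR-0 threshold from random tag placement, and a tag-density mode filter.
#
# For a small window of w bp inside a centered background window of B bp
# (clipped at contig edges), with n tags in the small window out of N in the
# background, the null is n ~ Binomial(N, p = w / B_effective) and the score
# is the normal approximation z = (n - N p) / sqrt(N p (1 - p)).

#' Default hotspot-calling parameters
#'
#' @param small_window scan window (bp).
#' @param background_window centered local-background window (bp).
#' @param step scan step (bp); must be <= `small_window`.
#' @param n_randomizations uniform tag placements used for the FDR-0
#'   threshold.
#' @param z_threshold fixed z cutoff; NULL (default) estimates the FDR-0
#'   threshold by randomization.
#' @param mode_filter apply the tag-density mode threshold.
#' @param mito_contig contig name excluded (and reported) as mitochondrial.
#' @return list of parameters for [call_hotspots()].
#' @export
hotspot_params <- function(small_window = 250, background_window = 200000,
                           step = 50, n_randomizations = 20,
                           z_threshold = NULL, mode_filter = TRUE,
                           mito_contig = "chrM") {
  stopifnot(small_window > 0, background_window > small_window,
            step > 0, step <= small_window, n_randomizations >= 1)
  list(small_window = as.integer(small_window),
       background_window = as.integer(background_window),
       step = as.integer(step),
       n_randomizations = as.integer(n_randomizations),
       z_threshold = z_threshold,
       mode_filter = mode_filter,
       mito_contig = mito_contig)
}

# scan core over per-contig sorted cut-site vectors
scan_cuts <- function(cuts_by_contig, genome_lengths, small_window,
                      background_window, step) {
  res <- lapply(names(genome_lengths), function(ctg) {
    L <- as.numeric(genome_lengths[[ctg]])
    cuts <- cuts_by_contig[[ctg]]
    if (is.null(cuts)) cuts <- numeric(0)
    ws <- seq(0, max(0, L - small_window), by = step)
    we <- pmin(ws + small_window, L)
    wlen <- we - ws
    center <- (ws + we) / 2
    bs <- pmax(0, center - background_window / 2)
    be <- pmin(L, center + background_window / 2)
    p <- wlen / (be - bs)
    n <- count_in_windows(cuts, ws, we)
    N <- count_in_windows(cuts, bs, be)
    keep <- N > 0 & p < 1
    z <- rep(NA_real_, length(ws))
    z[keep] <- (n[keep] - N[keep] * p[keep]) /
      sqrt(N[keep] * p[keep] * (1 - p[keep]))
    data.frame(contig = ctg, start = as.integer(ws), end = as.integer(we),
               n = n, N = N, p = p, z = z, stringsAsFactors = FALSE)[keep, ]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

split_cuts <- function(library) {
  t <- library$tags
  lapply(split(t$cut, t$contig), sort)
}

#' Per-window binomial z-scores of a tag library
#'
#' Scans each contig with windows of `small_window` bp stepped by `step` bp;
#' each window is scored against the tag count of a centered
#' `background_window` (clipped at contig edges, with the binomial p
#' recomputed from the clipped length). Windows with an empty background are
#' skipped.
#'
#' @param library a `tag_library`.
#' @param genome_lengths named contig-length vector.
#' @param small_window,background_window,step scan scales (bp).
#' @return data.frame with contig, start, end, n, N, p, z.
#' @export
scan_zscores <- function(library, genome_lengths, small_window = 250,
                         background_window = 200000, step = 50) {
  if (library_size(library) == 0) stopf("no tags")
  stopifnot(small_window < background_window, step <= small_window)
  scan_cuts(split_cuts(library), genome_lengths,
            small_window, background_window, step)
}

#' Empirical FDR-0 z threshold by random tag placement
#'
#' Places `library_size` tags uniformly over the genome `n_randomizations`
#' times, scans each placement, and returns the maximum observed random z
#' plus machine epsilon: the smallest threshold at which the expected number
#' of passing windows under the random model is zero.
#'
#' @param library_size number of tags to place.
#' @param genome_lengths named contig-length vector (nuclear contigs).
#' @param params parameters from [hotspot_params()].
#' @param seed RNG seed.
#' @return the z threshold (numeric scalar, attribute `max_random_z`).
#' @export
estimate_fdr0_threshold <- function(library_size, genome_lengths,
                                    params = hotspot_params(), seed = NULL) {
  gl <- as.numeric(genome_lengths)
  names(gl) <- names(genome_lengths)
  cum <- cumsum(gl)
  total <- cum[length(cum)]
  with_seed(seed, {
    max_z <- -Inf
    for (r in seq_len(params$n_randomizations)) {
      gpos <- floor(stats::runif(library_size, 0, total))
      ci <- findInterval(gpos, cum) + 1L
      local <- gpos - c(0, cum)[ci]
      cuts <- lapply(split(local, names(gl)[ci]), sort)
      sc <- scan_cuts(cuts, genome_lengths, params$small_window,
                      params$background_window, params$step)
      if (nrow(sc)) max_z <- max(max_z, sc$z)
    }
    thr <- max_z + 4 * .Machine$double.eps * max(1, abs(max_z))
    attr(thr, "max_random_z") <- max_z
    thr
  })
}

#' Call nuclease-accessibility hotspots
#'
#' Windows scoring at or above the FDR-0 threshold are merged when separated
#' by gaps of at most `small_window` bp; each merged interval is trimmed to
#' the span of the cut sites it contains; tag count, normalized density
#' (tags per kb per million library tags) and maximum window z are recorded;
#' finally the tag-density mode filter ([apply_mode_threshold()]) is
#' applied. Mitochondrial tags are excluded (and their fraction recorded)
#' before calling.
#'
#' @param library a `tag_library`.
#' @param genome_lengths named contig-length vector (may include the
#'   mitochondrial contig; it is dropped before scanning).
#' @param params parameters from [hotspot_params()].
#' @param seed RNG seed for the FDR randomizations.
#' @return a `hotspot_set`; `attr(, "params")` records the threshold, mode
#'   cutoff and mitochondrial fraction.
#' @export
call_hotspots <- function(library, genome_lengths, params = hotspot_params(),
                          seed = NULL) {
  if (library_size(library) == 0) stopf("no tags")
  mito_frac <- mito_fraction(library, params$mito_contig)
  nuc_gl <- genome_lengths[names(genome_lengths) != params$mito_contig]
  t <- library$tags[library$tags$contig != params$mito_contig, , drop = FALSE]
  if (nrow(t) == 0) stopf("no nuclear tags")
  lib_size <- nrow(t)
  cuts_by_contig <- lapply(split(t$cut, t$contig), sort)

  thr <- params$z_threshold
  if (is.null(thr)) {
    thr <- estimate_fdr0_threshold(lib_size, nuc_gl, params, seed = seed)
  }

  sc <- scan_cuts(cuts_by_contig, nuc_gl, params$small_window,
                  params$background_window, params$step)
  pass <- sc[!is.na(sc$z) & sc$z >= thr, , drop = FALSE]

  hs <- merge_and_trim(pass, cuts_by_contig, nuc_gl, params$small_window)
  if (nrow(hs)) {
    hs$density <- hs$tag_count / ((hs$end - hs$start) / 1000) /
      (lib_size / 1e6)
  } else {
    hs$density <- numeric(0)
  }
  set <- hotspot_set(hs, label = library$label,
                     params = c(params[c("small_window", "background_window",
                                         "step", "n_randomizations")],
                                list(z_threshold = as.numeric(thr),
                                     mito_fraction = mito_frac,
                                     library_size = lib_size)))
  if (isTRUE(params$mode_filter) && nrow(set) > 0) {
    set <- apply_mode_threshold(set)
  }
  set
}

# merge passing windows (gap <= merge_gap), trim to cut spans, count tags
merge_and_trim <- function(pass, cuts_by_contig, genome_lengths, merge_gap) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), tag_count = integer(), z = numeric())
  if (nrow(pass) == 0) return(empty)
  out <- list()
  for (ctg in unique(pass$contig)) {
    w <- pass[pass$contig == ctg, , drop = FALSE]
    w <- w[order(w$start), ]
    grp <- cumsum(c(1L, as.integer(w$start[-1] - w$end[-nrow(w)] > merge_gap)))
    cuts <- cuts_by_contig[[ctg]]
    L <- genome_lengths[[ctg]]
    merged <- lapply(split(seq_len(nrow(w)), grp), function(idx) {
      s <- w$start[idx[1]]
      e <- max(w$end[idx])
      lo <- findInterval(s - 0.5, cuts) + 1L
      hi <- findInterval(e - 0.5, cuts)
      if (hi < lo) return(NULL)
      tstart <- cuts[lo]
      tend <- min(cuts[hi] + 1L, L)
      if (tend <= tstart) tstart <- tend - 1L
      data.frame(contig = ctg, start = as.integer(tstart),
                 end = as.integer(tend), tag_count = hi - lo + 1L,
                 z = max(w$z[idx]), stringsAsFactors = FALSE)
    })
    out[[ctg]] <- do.call(rbind, merged)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Tag-density mode threshold
#'
#' Builds a histogram of log10(density) with bin width 0.1, locates the
#' modal bin and discards hotspots whose density falls below that bin's
#' lower edge. Density distributions of genuine hotspot sets span decades;
#' the log-scale mode separates the bulk of called regions from a low-density
#' shoulder.
#'
#' @param hotspots a `hotspot_set` with at least one hotspot.
#' @return the filtered `hotspot_set`; the cutoff is recorded in
#'   `attr(, "params")$mode_cutoff`.
#' @export
apply_mode_threshold <- function(hotspots) {
  if (nrow(hotspots) == 0) stopf("mode threshold requires >= 1 hotspot")
  params <- attr(hotspots, "params")
  if (nrow(hotspots) == 1) {
    params$mode_cutoff <- hotspots$density[1]
    attr(hotspots, "params") <- params
    return(hotspots)
  }
  ld <- log10(hotspots$density)
  bin <- as.integer(floor(ld / 0.1 + 1e-9))
  counts <- table(bin)
  modal_bin <- as.integer(names(counts)[which.max(counts)])
  cutoff_log <- modal_bin * 0.1
  keep <- ld >= cutoff_log - 1e-9
  params$mode_cutoff <- 10^cutoff_log
  out <- hotspots[keep, , drop = FALSE]
  hotspot_set(as.data.frame(out), params = params,
              label = attr(hotspots, "label"))
}

#' Mitochondrial tag fraction of a library
#'
#' @param library a `tag_library`.
#' @param mito_contig mitochondrial contig name.
#' @return share of tags aligned to `mito_contig` (0 for an empty library).
#' @export
mito_fraction <- function(library, mito_contig = "chrM") {
  n <- library_size(library)
  if (n == 0) return(0)
  sum(library$tags$contig == mito_contig) / n
}
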