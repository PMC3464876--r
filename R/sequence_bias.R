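# Enzyme sequence preference and base-composition structure: 5' cut-site
# base frequencies, GC content of interval classes, positional GC profiles
# and CpG island calling.

#' Base frequencies around tag cut sites
#'
#' For each tag the 2k bases centered on the cut site are read in the tag's
#' orientation (reverse complement for - tags): offset 0 is the first
#' sequenced base, negative offsets are upstream of the cut. Offsets that
#' fall outside the contig are excluded from that offset's denominator.
#'
#' @param library a `tag_library`.
#' @param genome genome as [Biostrings::DNAStringSet].
#' @param k flank (offsets -k .. k-1).
#' @return list of class `base_frequency_profile` with `offsets`, `freq`
#'   (4 x 2k matrix, rows A/C/G/T, columns per offset) and `n_tags`.
#' @export
cut_site_base_frequency <- function(library, genome, k = 10) {
  stopifnot(k >= 1)
  t <- library$tags
  gl <- genome_lengths(genome)
  windows <- character(nrow(t))
  for (ctg in unique(t$contig)) {
    idx <- which(t$contig == ctg)
    s <- as.character(genome[[ctg]])
    L <- gl[[ctg]]
    # plus-strand window [cut-k, cut+k) for + tags; for - tags the window
    # [cut-k, cut+k) read in reverse complement covers the same offsets
    ws <- t$cut[idx] - k
    we <- t$cut[idx] + k
    cs <- pmax(ws, 0L)
    ce <- pmin(we, L)
    body <- substring(s, cs + 1L, ce)
    windows[idx] <- paste0(strrep("N", cs - ws), body, strrep("N", we - ce))
  }
  set <- Biostrings::DNAStringSet(windows)
  minus <- t$strand == "-"
  if (any(minus)) {
    set[minus] <- Biostrings::reverseComplement(set[minus])
  }
  cm <- Biostrings::consensusMatrix(set, baseOnly = TRUE)
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  denom <- colSums(counts)
  freq <- sweep(counts, 2, pmax(denom, 1), "/")
  freq[, denom == 0] <- NA_real_
  colnames(freq) <- as.character(seq(-k, k - 1))
  structure(list(offsets = seq(-k, k - 1), freq = freq, n_tags = nrow(t)),
            class = "base_frequency_profile")
}

#' Per-interval GC fraction
#'
#' (G+C)/(A+C+G+T) per interval; N bases are excluded from the denominator.
#' Intervals consisting only of N yield NaN.
#'
#' @param intervals data.frame with contig, start, end (0-based half-open).
#' @param genome genome as [Biostrings::DNAStringSet].
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(intervals, genome) {
  out <- numeric(nrow(intervals))
  for (ctg in unique(intervals$contig)) {
    idx <- which(intervals$contig == ctg)
    v <- Biostrings::Views(genome[[ctg]], start = intervals$start[idx] + 1L,
                           end = intervals$end[idx])
    gc <- Biostrings::letterFrequency(v, "GC")[, 1]
    acgt <- Biostrings::letterFrequency(v, "ACGT")[, 1]
    out[idx] <- gc / acgt
  }
  out
}

#' Mean positional GC profile around anchors
#'
#' Anchors are centered on their midpoints; the mean GC fraction across
#' anchors is computed per bin of `bin_width` bp spanning +/- `flank`.
#' Anchors whose window leaves the contig are dropped.
#'
#' @param anchors data.frame with contig, start, end.
#' @param genome genome as [Biostrings::DNAStringSet].
#' @param flank half-window (bp), multiple of `bin_width`.
#' @param bin_width bin size (bp), default 10.
#' @return data.frame with `offset` (bin center relative to the anchor
#'   midpoint) and `gc`; attribute `n_anchors`.
#' @export
gc_profile_around <- function(anchors, genome, flank, bin_width = 10) {
  stopifnot(flank %% bin_width == 0)
  gl <- genome_lengths(genome)
  mid <- (anchors$start + anchors$end) %/% 2L
  ok <- mid - flank >= 0 & mid + flank <= gl[anchors$contig] &
    anchors$contig %in% names(gl)
  anchors <- anchors[ok, , drop = FALSE]
  mid <- mid[ok]
  if (!nrow(anchors)) stopf("no anchors fit within the genome")
  n_bins <- 2L * flank %/% bin_width
  sums <- numeric(n_bins)
  counts <- numeric(n_bins)
  for (ctg in unique(anchors$contig)) {
    idx <- which(anchors$contig == ctg)
    for (b in seq_len(n_bins)) {
      bs <- mid[idx] - flank + (b - 1L) * bin_width
      v <- Biostrings::Views(genome[[ctg]], start = bs + 1L,
                             end = bs + bin_width)
      gc <- Biostrings::letterFrequency(v, "GC")[, 1]
      acgt <- Biostrings::letterFrequency(v, "ACGT")[, 1]
      use <- acgt > 0
      sums[b] <- sums[b] + sum(gc[use] / acgt[use])
      counts[b] <- counts[b] + sum(use)
    }
  }
  structure(data.frame(offset = -flank + (seq_len(n_bins) - 0.5) * bin_width,
                       gc = sums / pmax(counts, 1)),
            n_anchors = nrow(anchors))
}

#' Call CpG islands by sliding-window criteria
#'
#' Finds maximal regions in which every 200 bp sliding window (step 1)
#' satisfies GC >= `min_gc` and CpG observed/expected =
#' (#CG dinucleotides * window length) / (#C * #G) >= `min_oe`; runs of
#' passing windows are merged and the merged regions filtered to length >=
#' `min_len`. Defaults are the classical Gardiner-Garden-Frommer thresholds.
#' Contigs shorter than the window are skipped.
#'
#' @param genome genome as [Biostrings::DNAStringSet].
#' @param min_len minimum island length (bp).
#' @param min_gc minimum window GC fraction.
#' @param min_oe minimum window CpG observed/expected ratio.
#' @param window evaluation window (bp).
#' @return data.frame with contig, start, end.
#' @export
find_cpg_islands <- function(genome, min_len = 200, min_gc = 0.5,
                             min_oe = 0.6, window = 200L) {
  out <- list()
  for (ctg in names(genome)) {
    codes <- codes_of(as.character(genome[[ctg]]))
    L <- length(codes)
    if (L < window) next
    isC <- codes == 2L
    isG <- codes == 3L
    cg <- isC[-L] & isG[-1]
    csC <- c(0, cumsum(isC))
    csG <- c(0, cumsum(isG))
    csCG <- c(0, cumsum(cg))
    starts0 <- 0:(L - window)           # 0-based window starts
    i <- starts0 + 1L                   # 1-based index into cumsums
    nC <- csC[i + window] - csC[i]
    nG <- csG[i + window] - csG[i]
    nCG <- csCG[i + window - 1L] - csCG[i]
    pass <- (nC + nG) >= min_gc * window - 1e-9 &
      nC > 0 & nG > 0 &
      nCG * window >= min_oe * nC * nG - 1e-9
    if (!any(pass)) next
    r <- rle(pass)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    runs <- which(r$values)
    isl <- data.frame(contig = ctg,
                      start = starts0[starts_idx[runs]],
                      end = starts0[ends_idx[runs]] + window,
                      stringsAsFactors = FALSE)
    isl <- isl[isl$end - isl$start >= min_len, , drop = FALSE]
    out[[ctg]] <- isl
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), start = integer(),
                      end = integer())
  }
  rownames(res) <- NULL
  res
}

#' Fraction of hotspots overlapping a CpG island
#'
#' @param hotspots a `hotspot_set` or data.frame with contig, start, end.
#' @param islands data.frame with contig, start, end.
#' @return share of hotspots overlapping (>= 1 bp) any island.
#' @export
cpg_overlap_fraction <- function(hotspots, islands) {
  if (nrow(hotspots) == 0) return(NaN)
  mean(overlaps_any(as.data.frame(hotspots), islands))
}
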