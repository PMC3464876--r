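# Cross-library hotspot comparison: union/Venn overlap, density-quartile
# parsing, quartile-resolved uniqueness and depth-invariant density
# correlations.

#' Merge hotspot sets into union intervals with per-source membership
#'
#' Intervals from all sets are merged wherever they overlap by >= 1 bp; each
#' union interval is flagged with every source set contributing a hotspot to
#' it. Venn-style counting is done over these union intervals, so split or
#' merged regions are not double-counted.
#'
#' @param sets named list of `hotspot_set` objects (>= 2 names).
#' @return data.frame with contig, start, end, one logical column per source
#'   and a `pattern` column (sorted source labels joined by "+").
#' @export
union_merge <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("union_merge requires a named list of hotspot sets")
  }
  all_df <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    data.frame(contig = s$contig, start = s$start, end = s$end,
               source = nm, stringsAsFactors = FALSE)
  }))
  if (nrow(all_df) == 0) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer())
    for (nm in names(sets)) out[[nm]] <- logical(0)
    out$pattern <- character(0)
    return(out)
  }
  gr <- as_granges(all_df)
  red <- GenomicRanges::reduce(gr)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    sub <- as_granges(sets[[nm]])
    out[[nm]] <- GenomicRanges::countOverlaps(red, sub) > 0
  }
  flags <- as.matrix(out[, names(sets), drop = FALSE])
  out$pattern <- apply(flags, 1, function(f) {
    paste(sort(names(sets)[f]), collapse = "+")
  })
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  out
}

#' Membership-pattern summary over union intervals
#'
#' @param sets named list of `hotspot_set` objects.
#' @return list with `per_source` counts, `union_count`, and a `patterns`
#'   data.frame (pattern, count, percent of union).
#' @export
overlap_summary <- function(sets) {
  if (length(sets) < 2) stopf("overlap_summary requires >= 2 sets")
  um <- union_merge(sets)
  pat <- table(um$pattern)
  patterns <- data.frame(pattern = names(pat),
                         count = as.integer(pat),
                         percent = 100 * as.integer(pat) / max(1, nrow(um)),
                         stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$count), ]
  rownames(patterns) <- NULL
  list(per_source = vapply(sets, nrow, integer(1)),
       union_count = nrow(um),
       patterns = patterns)
}

#' Parse a hotspot set into density quartiles
#'
#' Hotspots are sorted by density descending (ties broken by contig then
#' start, ascending) and split into four near-equal groups; quartile 1 holds
#' the most intense hotspots. When n is not divisible by 4 the top quartiles
#' take the extra members.
#'
#' @param set a `hotspot_set` with >= 4 hotspots.
#' @return the set's data.frame with an added integer `quartile` column,
#'   ordered by quartile then density.
#' @export
quartile_partition <- function(set) {
  n <- nrow(set)
  if (n < 4) stopf("quartile partition requires >= 4 hotspots")
  df <- as.data.frame(set)
  ord <- order(-df$density, df$contig, df$start)
  df <- df[ord, ]
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  df$quartile <- rep(1:4, times = sizes)
  rownames(df) <- NULL
  df
}

# TRUE for each row of `df` overlapping (>= 1 bp) any interval of `other`
overlaps_any <- function(df, other) {
  if (nrow(df) == 0) return(logical(0))
  if (nrow(other) == 0) return(rep(FALSE, nrow(df)))
  GenomicRanges::countOverlaps(as_granges(df), as_granges(other)) > 0
}

#' Per-quartile common vs unique hotspot fractions
#'
#' For each density quartile of `set`, the fraction of its hotspots
#' overlapping (>= 1 bp) any hotspot of any other set, and the complementary
#' unique fraction.
#'
#' @param set a `hotspot_set` (>= 4 hotspots).
#' @param other_sets list of `hotspot_set` objects to compare against.
#' @return data.frame with quartile (1 = most intense), n, common_fraction,
#'   unique_fraction.
#' @export
quartile_overlap <- function(set, other_sets) {
  qp <- quartile_partition(set)
  others <- do.call(rbind, lapply(other_sets, function(s) {
    data.frame(contig = s$contig, start = s$start, end = s$end)
  }))
  if (is.null(others)) others <- data.frame(contig = character(),
                                            start = integer(),
                                            end = integer())
  common <- overlaps_any(qp, others)
  agg <- vapply(1:4, function(q) {
    idx <- qp$quartile == q
    c(n = sum(idx), common = mean(common[idx]))
  }, numeric(2))
  data.frame(quartile = 1:4, n = as.integer(agg["n", ]),
             common_fraction = agg["common", ],
             unique_fraction = 1 - agg["common", ])
}

#' Normalized tag density of intervals
#'
#' @param library a `tag_library`.
#' @param regions data.frame with contig, start, end.
#' @return numeric vector of tags per kb per million library tags.
#' @export
region_density <- function(library, regions) {
  cuts <- split_cuts(library)
  libM <- library_size(library) / 1e6
  out <- numeric(nrow(regions))
  for (ctg in unique(regions$contig)) {
    idx <- which(regions$contig == ctg)
    cc <- cuts[[ctg]]
    if (is.null(cc)) cc <- numeric(0)
    n <- count_in_windows(cc, regions$start[idx], regions$end[idx])
    out[idx] <- n / ((regions$end[idx] - regions$start[idx]) / 1000) / libM
  }
  out
}

#' Density correlation of two libraries over a region set
#'
#' Computes the normalized tag density (tags/kb/million) of each region in
#' both libraries and returns the Pearson correlation of
#' log10(density + 0.1). The log scale keeps the coefficient from being
#' dominated by the few strongest regions; the pseudocount keeps empty
#' regions finite.
#'
#' @param libA,libB `tag_library` objects on the same genome.
#' @param regions data.frame with contig, start, end (e.g. union hotspots).
#' @return Pearson r (scalar).
#' @export
density_correlation <- function(libA, libB, regions) {
  if (nrow(regions) == 0) stopf("density_correlation requires regions")
  a <- log10(region_density(libA, regions) + 0.1)
  b <- log10(region_density(libB, regions) + 0.1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("degenerate density vector (zero variance)")
  }
  stats::cor(a, b)
}
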