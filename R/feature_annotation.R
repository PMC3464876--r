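# Relating hotspots and tag densities to genomic features: categorical
# classification against gene models, expression binning, TSS occupancy and
# positional aggregation profiles.

FEATURE_LEVELS <- c("promoter", "exon", "intron", "downstream", "distal")

#' Classify hotspots against gene models
#'
#' Each hotspot is classified by its midpoint with priority
#' promoter > exon > intron > downstream > distal. The promoter is the
#' `promoter_len` bp upstream of a TSS (strand-respecting), downstream the
#' `downstream_len` bp past the TTS, intron the gene body minus exons.
#'
#' @param hotspots a `hotspot_set` or data.frame with contig, start, end.
#' @param genes a `gene_models` data.frame ([read_gene_table()]).
#' @param promoter_len,downstream_len window sizes (bp), default 2000.
#' @return factor of categories, one per hotspot.
#' @export
classify_hotspots <- function(hotspots, genes, promoter_len = 2000,
                              downstream_len = 2000) {
  n <- nrow(hotspots)
  if (n == 0) return(factor(character(), levels = FEATURE_LEVELS))
  mid <- (hotspots$start + hotspots$end) %/% 2L
  pts <- GenomicRanges::GRanges(hotspots$contig,
                                IRanges::IRanges(mid + 1L, mid + 1L))
  plus <- genes$strand == "+"
  prom <- data.frame(
    contig = genes$contig,
    start = pmax(0L, ifelse(plus, genes$tss - promoter_len, genes$tss + 1L)),
    end = ifelse(plus, genes$tss, genes$tss + 1L + promoter_len)
  )
  exons <- do.call(rbind, Map(function(ctg, ex) {
    if (nrow(ex) == 0) return(NULL)
    data.frame(contig = ctg, start = ex$start, end = ex$end)
  }, genes$contig, parse_exons(genes$exons)))
  body <- data.frame(contig = genes$contig,
                     start = pmin(genes$tss, genes$tts),
                     end = pmax(genes$tss, genes$tts) + 1L)
  down <- data.frame(
    contig = genes$contig,
    start = pmax(0L, ifelse(plus, genes$tts + 1L, genes$tts - downstream_len)),
    end = ifelse(plus, genes$tts + 1L + downstream_len, genes$tts)
  )
  hit <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(rep(FALSE, n))
    df <- df[df$end > df$start, , drop = FALSE]
    if (nrow(df) == 0) return(rep(FALSE, n))
    GenomicRanges::countOverlaps(pts, as_granges(df)) > 0
  }
  in_prom <- hit(prom)
  in_exon <- hit(exons)
  in_body <- hit(body)
  in_down <- hit(down)
  cat <- rep("distal", n)
  cat[in_down] <- "downstream"
  cat[in_body] <- "intron"
  cat[in_exon] <- "exon"
  cat[in_prom] <- "promoter"
  factor(cat, levels = FEATURE_LEVELS)
}

#' Feature distribution of a hotspot set
#'
#' @inheritParams classify_hotspots
#' @return data.frame with category, count and fraction (fractions sum to 1
#'   for non-empty input).
#' @export
feature_distribution <- function(hotspots, genes, promoter_len = 2000,
                                 downstream_len = 2000) {
  cls <- classify_hotspots(hotspots, genes, promoter_len, downstream_len)
  counts <- table(cls)
  data.frame(category = FEATURE_LEVELS,
             count = as.integer(counts[FEATURE_LEVELS]),
             fraction = as.integer(counts[FEATURE_LEVELS]) /
               max(1L, length(cls)))
}

#' Bin genes by expression
#'
#' Two schemes: `"log2"` assigns detected genes to eight unit-log2 bins of
#' transcripts per cell (edges configurable, top bin open-ended) and
#' undetected genes (t = 0) to `"nd"`; `"decile"` ranks genes by expression
#' descending (ties by gene id, undetected last) and splits them into ten
#' near-equal groups, decile 1 the most expressed.
#'
#' @param expression data.frame with gene_id and transcripts_per_cell.
#' @param scheme "log2" or "decile".
#' @param log2_edges interior bin edges on the log2 scale (7 values giving 8
#'   bins).
#' @return data.frame with gene_id and `bin` (ordered factor, low to high
#'   expression; "nd" first for the log2 scheme).
#' @export
bin_expression <- function(expression, scheme = c("log2", "decile"),
                           log2_edges = c(-1, 0, 1, 2, 3, 4, 5)) {
  scheme <- match.arg(scheme)
  t <- expression$transcripts_per_cell
  if (any(t < 0)) stopf("negative expression value")
  if (scheme == "log2") {
    n_bins <- length(log2_edges) + 1L
    labels <- paste0("bin", seq_len(n_bins))
    bin <- rep(NA_character_, length(t))
    bin[t == 0] <- "nd"
    det <- t > 0
    bin[det] <- labels[findInterval(log2(t[det]), log2_edges,
                                    left.open = TRUE) + 1L]
    lev <- c("nd", labels)
  } else {
    ord <- order(-t, expression$gene_id)
    nq <- 10L
    n <- length(t)
    sizes <- rep(n %/% nq, nq)
    extra <- n %% nq
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    dec <- integer(n)
    dec[ord] <- rep(seq_len(nq), times = sizes)
    # decile 1 = most expressed; order factor low -> high expression
    bin <- paste0("decile", dec)
    lev <- paste0("decile", nq:1)
  }
  data.frame(gene_id = expression$gene_id,
             bin = factor(bin, levels = lev, ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' TSS hotspot occupancy per expression bin
#'
#' A gene counts as occupied when at least one of its TSSs (rows of the gene
#' table sharing its gene id) falls inside a hotspot of any provided set
#' (point-in-interval). Genes absent from the binning are assigned "nd".
#'
#' @param genes a `gene_models` data.frame.
#' @param hotspot_sets list of `hotspot_set` objects.
#' @param binning output of [bin_expression()] (log2 scheme).
#' @return data.frame with bin, n_genes, occupancy (fraction of genes in
#'   the bin with an accessible TSS), ordered "nd" then low to high.
#' @export
tss_occupancy <- function(genes, hotspot_sets, binning) {
  hs <- do.call(rbind, lapply(hotspot_sets, function(s) {
    data.frame(contig = s$contig, start = s$start, end = s$end)
  }))
  tss_pts <- data.frame(contig = genes$contig, start = genes$tss,
                        end = genes$tss + 1L)
  tss_hit <- overlaps_any(tss_pts, hs)
  occupied <- tapply(tss_hit, genes$gene_id, any)
  gene_ids <- names(occupied)
  bin <- binning$bin[match(gene_ids, binning$gene_id)]
  lev <- levels(binning$bin)
  bin <- as.character(bin)
  bin[is.na(bin)] <- "nd"
  bin <- factor(bin, levels = lev, ordered = TRUE)
  agg <- tapply(as.vector(occupied), bin, mean)
  cnt <- table(bin)
  data.frame(bin = factor(lev, levels = lev, ordered = TRUE),
             n_genes = as.integer(cnt[lev]),
             occupancy = as.numeric(agg[lev]))
}

# per-anchor x per-bin cut counts; offsets read 5'->3' of the anchor when
# strands are supplied (flipped for "-")
anchor_bin_counts <- function(points, strands, contigs, cuts_by_contig,
                              flank, bin_width) {
  n_bins <- 2L * flank %/% bin_width
  n <- length(points)
  m <- matrix(0, nrow = n, ncol = n_bins)
  for (ctg in unique(contigs)) {
    idx <- which(contigs == ctg)
    cc <- cuts_by_contig[[ctg]]
    if (is.null(cc)) cc <- numeric(0)
    for (b in seq_len(n_bins)) {
      o1 <- -flank + (b - 1L) * bin_width  # offset bin [o1, o1 + bin_width)
      plus <- strands[idx] != "-"
      # + / unstranded: cut - point in [o1, o2)  =>  cut in [p+o1, p+o2)
      # -            : point - cut in [o1, o2)  =>  cut in (p-o2, p-o1]
      bs <- ifelse(plus, points[idx] + o1, points[idx] - o1 - bin_width + 1L)
      m[idx, b] <- count_in_windows(cc, bs, bs + bin_width)
    }
  }
  m
}

#' Aggregate tag density around anchors
#'
#' Cut sites are tallied into offset bins relative to each anchor (the
#' interval midpoint, or the TSS with strand orientation), averaged over
#' anchors and normalized to tags per bp per million library tags.
#'
#' @param anchors data.frame with contig, start, end (midpoint mode) or a
#'   `gene_models` data.frame (tss mode).
#' @param library a `tag_library`.
#' @param flank half-window (bp), multiple of `bin_width`.
#' @param bin_width bin size (bp).
#' @param anchor_mode "midpoint" or "tss" (strand-oriented).
#' @return data.frame with `offset` (bin center) and `density`; attribute
#'   `n_anchors`.
#' @export
aggregate_density <- function(anchors, library, flank, bin_width = 50,
                              anchor_mode = c("midpoint", "tss")) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(flank %% bin_width == 0)
  if (nrow(anchors) == 0) stopf("no anchors")
  m <- density_heatmap_matrix(anchors, library, flank, bin_width, anchor_mode)
  structure(data.frame(offset = as.numeric(colnames(m)),
                       density = colMeans(m)),
            n_anchors = nrow(anchors))
}

#' Per-anchor tag density matrix (heatmap rows)
#'
#' One row per anchor, in the given (caller-ranked) order; cells are
#' normalized cut counts (tags per bp per million) per offset bin, i.e. the
#' rows of [aggregate_density()] before averaging.
#'
#' @inheritParams aggregate_density
#' @return numeric matrix, anchors x bins; column names are bin-center
#'   offsets.
#' @export
density_heatmap_matrix <- function(anchors, library, flank, bin_width = 50,
                                   anchor_mode = c("midpoint", "tss")) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(flank %% bin_width == 0)
  if (anchor_mode == "tss") {
    points <- anchors$tss
    strands <- anchors$strand
  } else {
    points <- (anchors$start + anchors$end) %/% 2L
    strands <- rep("+", nrow(anchors))
  }
  m <- anchor_bin_counts(points, strands, anchors$contig,
                         split_cuts(library), flank, bin_width)
  m <- m / bin_width / (library_size(library) / 1e6)
  n_bins <- ncol(m)
  colnames(m) <- as.character(-flank + (seq_len(n_bins) - 0.5) * bin_width)
  m
}
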