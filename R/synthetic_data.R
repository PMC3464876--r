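# Synthetic nuclease-digestion data: random genomes with GC structure and
# planted CpG islands, accessibility landscapes with expression-coupled
# promoter regions, and a fragment-level digestion simulator with
# enzyme-specific cut-site base preferences.

BASES <- c("A", "C", "G", "T")
MITO_CONTIG <- "chrM"

#' Preset enzyme cut-site bias models
#'
#' Relative per-base cut propensities at the cleavage position. Benzonase and
#' Cyanase share a G/C-skewed preset (G strongest); DNase I is T-skewed; the
#' uniform preset has no preference. Only the direction of the skew is a
#' biochemical fact; the magnitudes are calibration values and can be
#' overridden by constructing the list directly.
#'
#' @param name one of "benzonase", "cyanase", "dnase1", "uniform".
#' @return list with `name` and `base_weights` (named, summing to 1).
#' @export
preset_bias <- function(name) {
  presets <- list(
    uniform   = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    benzonase = c(A = 0.15, C = 0.30, G = 0.40, T = 0.15),
    cyanase   = c(A = 0.15, C = 0.30, G = 0.40, T = 0.15),
    dnase1    = c(A = 0.20, C = 0.15, G = 0.15, T = 0.50)
  )
  if (!name %in% names(presets)) {
    stopf("unknown bias preset '%s'; available: %s", name,
          paste(names(presets), collapse = ", "))
  }
  list(name = name, base_weights = presets[[name]])
}

# integer codes 1..4 for A,C,G,T; 0 for anything else (N)
codes_of <- function(seq_string) {
  lut <- integer(256)
  lut[utf8ToInt("A") + 1L] <- 1L
  lut[utf8ToInt("C") + 1L] <- 2L
  lut[utf8ToInt("G") + 1L] <- 3L
  lut[utf8ToInt("T") + 1L] <- 4L
  lut[as.integer(charToRaw(seq_string)) + 1L]
}

codes_to_string <- function(codes) {
  intToUtf8(c(utf8ToInt("N"), utf8ToInt("A"), utf8ToInt("C"),
              utf8ToInt("G"), utf8ToInt("T"))[codes + 1L])
}

# i.i.d. base codes with P(G)=P(C)=gc/2 per position (gc may be a vector)
random_codes <- function(n, gc) {
  is_gc <- stats::runif(n) < gc
  coin <- stats::runif(n) < 0.5
  ifelse(is_gc, ifelse(coin, 2L, 3L), ifelse(coin, 1L, 4L))
}

#' Generate a random genome with GC block structure and planted CpG islands
#'
#' Nuclear contigs are assembled from i.i.d.-base blocks whose GC fraction is
#' drawn per block from `gc_levels`, emulating isochore-like composition
#' variation. `n_cpg_islands` segments of 500-1500 bp with GC ~0.7 and CpG
#' observed/expected ~1 (i.i.d. draws at P(C)=P(G)=0.35) are planted at
#' non-overlapping recorded positions. A 16 kb mitochondrial contig
#' (`chrM`, uniform 40% GC) is appended so mitochondrial-fraction reporting
#' can be exercised.
#'
#' @param n_contigs number of nuclear contigs.
#' @param contig_len length of each nuclear contig (bp).
#' @param gc_block_len block length for GC level switching (bp).
#' @param gc_levels GC fractions sampled per block, each in (0,1).
#' @param n_cpg_islands islands planted across nuclear contigs.
#' @param include_mito append the `chrM` contig (default TRUE).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return a [Biostrings::DNAStringSet] with attribute `cpg_islands`
#'   (data.frame contig/start/end of planted islands).
#' @export
generate_genome <- function(n_contigs = 2, contig_len = 5e6,
                            gc_block_len = 20000,
                            gc_levels = c(0.35, 0.45, 0.55),
                            n_cpg_islands = 100, include_mito = TRUE,
                            seed = NULL) {
  stopifnot(n_contigs >= 1, contig_len > 0, gc_block_len > 0,
            all(gc_levels > 0 & gc_levels < 1))
  with_seed(seed, {
    contigs <- character(n_contigs)
    islands <- list()
    per_contig <- diff(round(seq(0, n_cpg_islands, length.out = n_contigs + 1)))
    for (ci in seq_len(n_contigs)) {
      n_blocks <- ceiling(contig_len / gc_block_len)
      block_gc <- sample(gc_levels, n_blocks, replace = TRUE)
      gc_per_pos <- rep(block_gc, each = gc_block_len)[seq_len(contig_len)]
      codes <- random_codes(contig_len, gc_per_pos)
      k <- per_contig[ci]
      if (k > 0) {
        lens <- as.integer(round(stats::runif(k, 500, 1500)))
        if (sum(lens) > contig_len) stopf("island total length exceeds contig")
        starts <- place_nonoverlapping(contig_len, lens, n_tries = 1000L)
        for (j in seq_len(k)) {
          idx <- (starts[j] + 1L):(starts[j] + lens[j])
          codes[idx] <- random_codes(lens[j], 0.7)
        }
        islands[[ci]] <- data.frame(contig = sprintf("chr%d", ci),
                                    start = starts, end = starts + lens)
      }
      contigs[ci] <- codes_to_string(codes)
    }
    names(contigs) <- sprintf("chr%d", seq_len(n_contigs))
    if (include_mito) {
      contigs[MITO_CONTIG] <- codes_to_string(random_codes(16299L, 0.40))
    }
    genome <- Biostrings::DNAStringSet(contigs)
    isl <- if (length(islands)) do.call(rbind, islands) else
      data.frame(contig = character(), start = integer(), end = integer())
    isl <- isl[order(isl$contig, isl$start), , drop = FALSE]
    rownames(isl) <- NULL
    attr(genome, "cpg_islands") <- isl
    genome
  })
}

# sample `length(lens)` non-overlapping 0-based starts on [0, total_len),
# greedily with bounded per-region retries
place_nonoverlapping <- function(total_len, lens, n_tries = 1000L) {
  k <- length(lens)
  acc_s <- numeric(0)
  acc_e <- numeric(0)
  out <- integer(k)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (attempt in seq_len(n_tries)) {
      s <- floor(stats::runif(1, 0, total_len - lens[i]))
      j <- findInterval(s, acc_s)
      ok <- (j < 1 || acc_e[j] <= s) &&
        (j >= length(acc_s) || acc_s[j + 1] >= s + lens[i])
      if (ok) {
        acc_s <- append(acc_s, s, after = j)
        acc_e <- append(acc_e, s + lens[i], after = j)
        out[i] <- as.integer(s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("could not place %d non-overlapping regions after %d attempts",
            k, n_tries)
    }
  }
  out
}

#' Generate an accessibility landscape with expression-coupled genes
#'
#' Places `n_regions` non-overlapping accessible regions uniformly on the
#' nuclear contigs with log-normal cut-rate intensities. A `promoter_fraction`
#' share of regions each spawn a gene whose TSS lies inside the region and
#' whose expression follows
#' `transcripts_per_cell = expression_coupling * intensity * exp(eps)`,
#' `eps ~ Normal(0, 0.5)`; an equal number of silent genes
#' (`transcripts_per_cell = 0`) is placed with TSSs in unplanted sequence.
#'
#' @param genome genome the landscape is bound to.
#' @param n_regions number of accessible regions.
#' @param intensity_law list with `meanlog`, `sdlog` of the log-normal
#'   intensity distribution (clamped below at 1, the baseline).
#' @param promoter_fraction share of regions that carry a gene TSS.
#' @param expression_coupling scale linking intensity to expression; 0
#'   decouples them.
#' @param region_len_range min/max region width (bp).
#' @param gene_len_range min/max gene length (bp).
#' @param silent_margin minimum distance (bp) between a silent gene's TSS
#'   and any accessible region; keeps silent promoters in genuinely closed
#'   chromatin, clear of the fragment-length smear around planted regions.
#' @param seed RNG seed.
#' @return list with `landscape` (list of `regions` data.frame and
#'   `baseline_rate`), `genes` (gene_models data.frame) and `expression`
#'   (gene_id / transcripts_per_cell data.frame).
#' @export
generate_landscape <- function(genome, n_regions = 200,
                               intensity_law = list(meanlog = log(8), sdlog = 0.8),
                               promoter_fraction = 0.5,
                               expression_coupling = 2,
                               region_len_range = c(200, 1000),
                               gene_len_range = c(2000, 20000),
                               silent_margin = 1500,
                               seed = NULL) {
  gl <- genome_lengths(genome)
  nuclear <- names(gl)[names(gl) != MITO_CONTIG]
  with_seed(seed, {
    per_contig <- as.vector(stats::rmultinom(1, n_regions,
                                             gl[nuclear] / sum(gl[nuclear])))
    regs <- list()
    for (i in seq_along(nuclear)) {
      k <- per_contig[i]
      if (k == 0) next
      lens <- as.integer(round(stats::runif(k, region_len_range[1],
                                            region_len_range[2])))
      starts <- place_nonoverlapping(gl[nuclear[i]], lens)
      regs[[i]] <- data.frame(contig = nuclear[i], start = starts,
                              end = starts + lens)
    }
    regions <- do.call(rbind, regs)
    regions <- regions[order(regions$contig, regions$start), ]
    rownames(regions) <- NULL
    regions$intensity <- pmax(1, stats::rlnorm(nrow(regions),
                                               intensity_law$meanlog,
                                               intensity_law$sdlog))
    n_prom <- round(promoter_fraction * nrow(regions))
    prom_idx <- sort(sample.int(nrow(regions), n_prom))
    regions$klass <- "enhancer"
    regions$klass[prom_idx] <- "promoter"

    genes <- make_genes(regions[prom_idx, , drop = FALSE], gl, gene_len_range,
                        id_offset = 0L)
    silent <- make_silent_genes(n_prom, regions, gl[nuclear], gene_len_range,
                                id_offset = n_prom,
                                margin = silent_margin)
    all_genes <- rbind(genes, silent)
    class(all_genes) <- c("gene_models", "data.frame")
    eps <- stats::rnorm(n_prom, 0, 0.5)
    expr <- data.frame(
      gene_id = c(genes$gene_id,  silent$gene_id),
      transcripts_per_cell = c(
        expression_coupling * regions$intensity[prom_idx] * exp(eps),
        rep(0, nrow(silent))
      )
    )
    list(landscape = list(regions = regions, baseline_rate = 1),
         genes = all_genes, expression = expr)
  })
}

# one gene per region row; TSS uniform inside the region
make_genes <- function(regions, gl, gene_len_range, id_offset) {
  n <- nrow(regions)
  if (n == 0) {
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), tss = integer(), tts = integer(),
                      exons = character()))
  }
  tss <- as.integer(floor(stats::runif(n, regions$start, regions$end)))
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  glen <- as.integer(round(stats::runif(n, gene_len_range[1],
                                        gene_len_range[2])))
  contig_len <- gl[regions$contig]
  tts <- ifelse(strand == "+",
                pmin(tss + glen, contig_len - 1L),
                pmax(tss - glen, 0L))
  exons <- vapply(seq_len(n), function(i) {
    make_exon_string(min(tss[i], tts[i]), max(tss[i], tts[i]))
  }, character(1))
  data.frame(gene_id = sprintf("g%04d", id_offset + seq_len(n)),
             contig = regions$contig, strand = strand,
             tss = tss, tts = as.integer(tts), exons = exons,
             stringsAsFactors = FALSE)
}

# alternating exon/intron walk over the gene span; always >= 1 exon
make_exon_string <- function(span_start, span_end) {
  pos <- span_start
  ex <- character(0)
  repeat {
    elen <- as.integer(round(stats::runif(1, 100, 400)))
    eend <- min(pos + elen, span_end + 1L)
    if (eend > pos) ex <- c(ex, sprintf("%d-%d", pos, eend))
    pos <- eend + as.integer(round(stats::runif(1, 300, 2000)))
    if (pos >= span_end) break
  }
  paste(ex, collapse = ",")
}

make_silent_genes <- function(n, regions, nuclear_gl, gene_len_range,
                              id_offset, margin = 1500) {
  if (n == 0) {
    return(make_genes(regions[0, ], nuclear_gl, gene_len_range, id_offset))
  }
  contigs <- sample(names(nuclear_gl), n, replace = TRUE,
                    prob = nuclear_gl / sum(nuclear_gl))
  tss <- integer(n)
  for (i in seq_len(n)) {
    for (attempt in 1:1000) {
      cand <- as.integer(floor(stats::runif(1, 0, nuclear_gl[contigs[i]])))
      hit <- regions$contig == contigs[i] &
        cand >= regions$start - margin & cand < regions$end + margin
      if (!any(hit)) {
        tss[i] <- cand
        break
      }
      if (attempt == 1000) stopf("could not place silent gene TSS")
    }
  }
  fake_regions <- data.frame(contig = contigs, start = tss, end = tss + 1L)
  g <- make_genes(fake_regions, nuclear_gl, gene_len_range, id_offset)
  g
}

#' Simulate nuclease digestion of a genome into a tag library
#'
#' Fragment-level model of partial digestion followed by size selection and
#' single-end sequencing. Per fragment: the first cut position is drawn with
#' probability proportional to `landscape rate x base_weights(base)`; the
#' second cut is drawn from positions `min_len..max_len` bp downstream on the
#' same contig with the same weighting (bias read on the strand being cut,
#' i.e. the reverse complement base for the downstream cut); one end is
#' chosen by a fair coin and a tag of `tag_len` bp is emitted from that cut
#' inward, strand set so its 5' end is the cut site. A `mito_fraction` share
#' of fragments is instead placed uniformly on the `chrM` contig.
#'
#' @param genome genome as [Biostrings::DNAStringSet].
#' @param landscape accessibility landscape (`regions` + `baseline_rate`);
#'   NULL means flat baseline.
#' @param bias an [preset_bias()] model (or equivalent list).
#' @param n_fragments number of fragments (= tags) to emit.
#' @param fragment_model list with `min_len`, `max_len` (bp); the 100-500 bp
#'   default mirrors gel/gradient size selection.
#' @param tag_len sequenced tag length (bp); must be < `min_len`.
#' @param mito_fraction share of fragments drawn from `chrM`.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param label library label.
#' @return a `tag_library`.
#' @export
simulate_digestion <- function(genome, landscape, bias, n_fragments,
                               fragment_model = list(min_len = 100, max_len = 500),
                               tag_len = 36, mito_fraction = 0,
                               seed = NULL, label = bias$name) {
  stopifnot(fragment_model$min_len > 0,
            fragment_model$min_len < fragment_model$max_len,
            tag_len < fragment_model$min_len,
            mito_fraction >= 0, mito_fraction < 1)
  gl <- genome_lengths(genome)
  nuclear <- names(gl)[names(gl) != MITO_CONTIG]
  if (mito_fraction > 0 && !MITO_CONTIG %in% names(gl)) {
    stopf("mito_fraction > 0 but genome has no '%s' contig", MITO_CONTIG)
  }
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character())
  if (n_fragments == 0) return(tag_library(empty, label = label))

  bw <- bias$base_weights[BASES]
  bw_comp <- bw[c("T", "G", "C", "A")] # weight of the complement base
  min_len <- as.integer(fragment_model$min_len)
  max_len <- as.integer(fragment_model$max_len)

  # per-base rate from the landscape, baseline elsewhere
  baseline <- if (is.null(landscape)) 1 else landscape$baseline_rate
  regions <- if (is.null(landscape)) NULL else landscape$regions

  codes_all <- integer(0)
  rate_all <- numeric(0)
  contig_of <- integer(0)
  for (i in seq_along(nuclear)) {
    ctg <- nuclear[i]
    codes <- codes_of(as.character(genome[[ctg]]))
    rate <- rep(baseline, length(codes))
    if (!is.null(regions)) {
      rr <- regions[regions$contig == ctg, , drop = FALSE]
      for (j in seq_len(nrow(rr))) {
        rate[(rr$start[j] + 1L):rr$end[j]] <- rr$intensity[j]
      }
    }
    codes_all <- c(codes_all, codes)
    rate_all <- c(rate_all, rate)
    contig_of <- c(contig_of, rep(i, length(codes)))
  }
  cum_end <- cumsum(gl[nuclear])          # global 1-based end index per contig
  cum_start <- c(0, cum_end[-length(cum_end)]) # global offset per contig

  wb <- c(0, bw)[codes_all + 1L]          # N bases get weight 0
  wbc <- c(0, bw_comp)[codes_all + 1L]
  Wp <- cumsum(rate_all * wb)
  Wm <- cumsum(rate_all * wbc)
  rm(wb, wbc, rate_all, codes_all)
  Wp_tot <- Wp[length(Wp)]
  if (Wp_tot <= 0) stopf("genome has no cuttable base")

  with_seed(seed, {
    n_mito <- if (mito_fraction > 0) {
      stats::rbinom(1, n_fragments, mito_fraction)
    } else 0L
    n_nuc <- n_fragments - n_mito

    first <- integer(n_nuc)  # global 1-based first-cut index
    second <- integer(n_nuc)
    todo <- seq_len(n_nuc)
    for (round in 1:50) {
      if (!length(todo)) break
      u <- stats::runif(length(todo), 0, Wp_tot)
      p <- findInterval(u, Wp) + 1L
      ci <- contig_of[p]
      a <- p + min_len - 1L
      b <- pmin(p + max_len - 1L, cum_end[ci])
      ok <- a <= b
      wa <- rep(0, length(todo))
      wa[ok] <- Wm[b[ok]] - Wm[a[ok] - 1L]
      ok <- ok & wa > 0
      if (any(ok)) {
        u2 <- Wm[a[ok] - 1L] + pmax(stats::runif(sum(ok)), 1e-12) * wa[ok]
        q <- findInterval(u2, Wm) + 1L
        q <- pmax(a[ok], pmin(q, b[ok]))
        first[todo[ok]] <- p[ok]
        second[todo[ok]] <- q
      }
      todo <- todo[!ok]
      if (round == 50 && length(todo)) {
        stopf("no admissible second cut after bounded retries")
      }
    }

    ci <- contig_of[first]
    local_p <- first - cum_start[ci] - 1L   # 0-based first-cut base index
    local_q <- second - cum_start[ci] - 1L  # 0-based second-cut base index
    plus_end <- stats::runif(n_nuc) < 0.5
    start <- ifelse(plus_end, local_p, local_q + 1L - tag_len)
    end <- start + tag_len
    tags <- data.frame(contig = nuclear[ci], start = as.integer(start),
                       end = as.integer(end),
                       strand = ifelse(plus_end, "+", "-"),
                       stringsAsFactors = FALSE)

    if (n_mito > 0) {
      L <- gl[[MITO_CONTIG]]
      ms <- as.integer(floor(stats::runif(n_mito, 0, L - tag_len)))
      tags <- rbind(tags, data.frame(
        contig = MITO_CONTIG, start = ms, end = ms + tag_len,
        strand = ifelse(stats::runif(n_mito) < 0.5, "+", "-"),
        stringsAsFactors = FALSE
      ))
    }
    tag_library(tags, label = label, genome_lengths = gl)
  })
}
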