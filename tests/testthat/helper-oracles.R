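# Independent brute-force oracles. These are deliberately written as plain
# loops over the definitions, sharing no code path with the package
# implementation they check.

oracle_scan <- function(cuts, L, small, bg, step) {
  out <- list()
  for (ws in seq(0, max(0, L - small), by = step)) {
    we <- min(ws + small, L)
    center <- (ws + we) / 2
    bs <- max(0, center - bg / 2)
    be <- min(L, center + bg / 2)
    n <- sum(cuts >= ws & cuts < we)
    N <- sum(cuts >= bs & cuts < be)
    p <- (we - ws) / (be - bs)
    if (N == 0 || p >= 1) next
    z <- (n - N * p) / sqrt(N * p * (1 - p))
    out[[length(out) + 1L]] <- data.frame(start = ws, end = we, n = n,
                                          N = N, z = z)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), n = integer(),
                      N = integer(), z = numeric()))
  }
  do.call(rbind, out)
}

oracle_hotspots <- function(cuts, L, small, bg, step, thr) {
  sc <- oracle_scan(cuts, L, small, bg, step)
  pass <- sc[sc$z >= thr, , drop = FALSE]
  empty <- data.frame(start = integer(), end = integer(),
                      tag_count = integer(), z = numeric())
  if (nrow(pass) == 0) return(empty)
  groups <- list()
  cur <- pass[1, ]
  cur_zmax <- cur$z
  for (i in seq_len(nrow(pass))[-1]) {
    row <- pass[i, ]
    if (row$start - cur$end <= small) {
      cur$end <- max(cur$end, row$end)
      cur_zmax <- max(cur_zmax, row$z)
    } else {
      groups[[length(groups) + 1L]] <- c(cur$start, cur$end, cur_zmax)
      cur <- row
      cur_zmax <- row$z
    }
  }
  groups[[length(groups) + 1L]] <- c(cur$start, cur$end, cur_zmax)
  out <- list()
  for (g in groups) {
    cs <- cuts[cuts >= g[1] & cuts < g[2]]
    if (!length(cs)) next
    tstart <- min(cs)
    tend <- min(max(cs) + 1, L)
    if (tend <= tstart) tstart <- tend - 1
    out[[length(out) + 1L]] <- data.frame(start = tstart, end = tend,
                                          tag_count = length(cs), z = g[3])
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# base-resolution union membership for interval sets on one small contig
oracle_union_membership <- function(sets, L) {
  cov <- lapply(sets, function(df) {
    v <- logical(L)
    for (i in seq_len(nrow(df))) {
      v[(df$start[i] + 1):df$end[i]] <- TRUE
    }
    v
  })
  any_cov <- Reduce(`|`, cov)
  r <- rle(any_cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    flags <- vapply(cov, function(v) any(v[starts[k]:ends[k]]), logical(1))
    out[[length(out) + 1L]] <- data.frame(
      start = starts[k] - 1L, end = ends[k],
      pattern = paste(sort(names(sets)[flags]), collapse = "+"))
  }
  do.call(rbind, out)
}

# per-offset base counting by direct character manipulation
oracle_base_freq <- function(tags, seq_string, k) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  counts <- matrix(0, nrow = 4, ncol = 2 * k,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  L <- nchar(seq_string)
  for (i in seq_len(nrow(tags))) {
    cut <- tags$cut[i]
    for (off in seq(-k, k - 1)) {
      gpos <- if (tags$strand[i] == "+") cut + off else cut - 1 - off
      if (gpos < 0 || gpos >= L) next
      b <- substr(seq_string, gpos + 1, gpos + 1)
      if (tags$strand[i] == "-") b <- comp[[b]]
      if (b %in% rownames(counts)) {
        counts[b, off + k + 1] <- counts[b, off + k + 1] + 1
      }
    }
  }
  counts
}

# direct sliding-window CpG island evaluation
oracle_cpg <- function(seq_string, min_len = 200, min_gc = 0.5,
                       min_oe = 0.6, window = 200) {
  L <- nchar(seq_string)
  if (L < window) {
    return(data.frame(start = integer(), end = integer()))
  }
  chars <- strsplit(seq_string, "")[[1]]
  pass <- logical(L - window + 1)
  for (s in seq_len(L - window + 1)) {
    win <- chars[s:(s + window - 1)]
    nC <- sum(win == "C")
    nG <- sum(win == "G")
    nCG <- sum(win[-window] == "C" & win[-1] == "G")
    pass[s] <- (nC + nG) >= min_gc * window - 1e-9 && nC > 0 && nG > 0 &&
      nCG * window >= min_oe * nC * nG - 1e-9
  }
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = starts[keep] - 1L,
                    end = ends[keep] - 1L + window)
  out[out$end - out$start >= min_len, , drop = FALSE]
}

# pairwise >=1 bp overlap check by direct looping
overlaps_any_df <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$contig == a$contig[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# uniform random tag library on a given genome-lengths vector
uniform_library <- function(n, genome_lengths, tag_len = 36, seed = NULL,
                            label = "uniform") {
  make <- function() {
    gl <- as.numeric(genome_lengths)
    cum <- cumsum(gl)
    gpos <- floor(runif(n, 0, cum[length(cum)]))
    ci <- findInterval(gpos, cum) + 1L
    local <- gpos - c(0, cum)[ci]
    start <- pmin(local, gl[ci] - tag_len)
    data.frame(contig = names(genome_lengths)[ci],
               start = as.integer(start),
               end = as.integer(start + tag_len),
               strand = "+")
  }
  tags <- if (is.null(seed)) make() else tachseq:::with_seed(seed, make())
  tag_library(tags, label = label)
}
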