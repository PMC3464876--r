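# Internal helpers shared across modules.

# All coordinates in this package follow the BED convention: 0-based,
# half-open [start, end). Conversion to the 1-based closed convention of
# IRanges/GenomicRanges happens only inside these helpers.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Count, for each [start_i, end_i) query, the sorted integer positions
# falling inside it. `pos_sorted` must be sorted non-decreasing.
count_in_windows <- function(pos_sorted, starts, ends) {
  findInterval(ends - 0.5, pos_sorted) - findInterval(starts - 0.5, pos_sorted)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Contig lengths of a genome
#'
#' @param genome a [Biostrings::DNAStringSet] as returned by [read_fasta()] or
#'   [generate_genome()].
#' @return named integer vector of contig lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
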