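# Readers and writers for the external formats the pipeline touches:
# FASTA genomes, BED6 tag/anchor/hotspot intervals, the gene-model TSV and
# the expression TSV. All interval I/O is 0-based half-open (BED).

#' Read a genome from FASTA
#'
#' Loads every record, folds lowercase to uppercase and maps any character
#' outside A/C/G/T/N to N.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet], one entry per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stopf("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stopf("duplicate contig name in %s: %s", path, nm[duplicated(nm)][1])
  }
  if (any(!nzchar(nm))) stopf("empty contig name in %s", path)
  chars <- toupper(as.character(seqs))
  chars <- gsub("[^ACGTN]", "N", chars)
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- nm
  if (any(Biostrings::width(out) == 0)) stopf("zero-length contig in %s", path)
  out
}

#' Write a genome to FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Construct a tag library
#'
#' A tag library holds aligned single-end sequence tags whose 5' ends mark
#' nuclease cut sites: the cut site of a + tag is its start coordinate, the
#' cut site of a - tag its (exclusive) end coordinate.
#'
#' @param tags data.frame with columns contig, start, end, strand.
#' @param label free-text label (enzyme, concentration, depth...).
#' @param genome_lengths optional named vector; when given, tags are checked
#'   against contig bounds.
#' @return an object of class `tag_library`.
#' @export
tag_library <- function(tags, label = "", genome_lengths = NULL) {
  need <- c("contig", "start", "end", "strand")
  if (!all(need %in% names(tags))) {
    stopf("tag table must have columns %s", paste(need, collapse = ", "))
  }
  tags$contig <- as.character(tags$contig)
  tags$start <- as.integer(tags$start)
  tags$end <- as.integer(tags$end)
  tags$strand <- as.character(tags$strand)
  if (any(!tags$strand %in% c("+", "-"))) {
    stopf("tags must be stranded (+ or -); found '%s'",
          setdiff(unique(tags$strand), c("+", "-"))[1])
  }
  bad <- which(tags$start < 0L | tags$start >= tags$end)
  if (length(bad)) stopf("invalid tag interval at record %d", bad[1])
  if (!is.null(genome_lengths)) {
    unk <- setdiff(unique(tags$contig), names(genome_lengths))
    if (length(unk)) stopf("tag on unknown contig: %s", unk[1])
    over <- which(tags$end > genome_lengths[tags$contig])
    if (length(over)) stopf("tag beyond contig end at record %d", over[1])
  }
  tags$cut <- ifelse(tags$strand == "+", tags$start, tags$end)
  rownames(tags) <- NULL
  structure(
    list(tags = tags[, c("contig", "start", "end", "strand", "cut")],
         label = label),
    class = "tag_library"
  )
}

#' Number of tags in a library
#' @param library a `tag_library`.
#' @export
library_size <- function(library) nrow(library$tags)

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d tags on %d contig(s)\n",
              x$label, library_size(x), length(unique(x$tags$contig))))
  invisible(x)
}

#' Read aligned tags from BED
#'
#' Accepts BED6 (strand in column 6) or BED3+strand (strand in column 4).
#' Unstranded records ('.') are rejected because the cut-site definition
#' depends on strand.
#'
#' @param path BED file path.
#' @param genome_lengths optional named contig-length vector for validation.
#' @param label library label; defaults to the file name.
#' @return a `tag_library`.
#' @export
read_tags_bed <- function(path, genome_lengths = NULL, label = basename(path)) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  strand_col <- if (ncol(df) >= 6) 6L else if (ncol(df) == 4) 4L else
    stopf("%s: expected BED6 or BED3+strand, got %d columns", path, ncol(df))
  start <- suppressWarnings(as.integer(df[[2]]))
  end <- suppressWarnings(as.integer(df[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stopf("%s line %d: invalid interval", path, bad[1])
  strand <- df[[strand_col]]
  nostr <- which(!strand %in% c("+", "-"))
  if (length(nostr)) stopf("%s line %d: unstranded tag rejected", path, nostr[1])
  tag_library(data.frame(contig = df[[1]], start = start, end = end,
                         strand = strand, stringsAsFactors = FALSE),
              label = label, genome_lengths = genome_lengths)
}

#' Write a tag library to BED6
#' @param library a `tag_library`.
#' @param path output path.
#' @export
write_tags_bed <- function(library, path) {
  t <- library$tags
  out <- data.frame(t$contig, t$start, t$end,
                    paste0("tag_", seq_len(nrow(t))), 0L, t$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a hotspot set
#'
#' @param hotspots data.frame with columns contig, start, end, tag_count,
#'   density (tags/kb/million library tags), z (max window z-score).
#' @param params list of calling parameters, recorded with the set.
#' @param label source library label.
#' @return an object of class `hotspot_set` (a data.frame).
#' @export
hotspot_set <- function(hotspots, params = list(), label = "") {
  need <- c("contig", "start", "end", "tag_count", "density", "z")
  if (!all(need %in% names(hotspots))) {
    stopf("hotspot table must have columns %s", paste(need, collapse = ", "))
  }
  hotspots <- hotspots[order(hotspots$contig, hotspots$start), need]
  rownames(hotspots) <- NULL
  if (nrow(hotspots) > 1) {
    same <- hotspots$contig[-1] == hotspots$contig[-nrow(hotspots)]
    if (any(same & hotspots$start[-1] < hotspots$end[-nrow(hotspots)])) {
      stopf("hotspots must be non-overlapping")
    }
  }
  structure(hotspots, params = params, label = label,
            class = c("hotspot_set", "data.frame"))
}

#' Write hotspots to BED5+
#'
#' Columns: contig, start, end, name, density (3 decimals, BED score slot),
#' strand ('.'), z-score. Sorted by contig then start.
#'
#' @param set a `hotspot_set`.
#' @param path output path.
#' @export
write_hotspots_bed <- function(set, path) {
  if (nrow(set) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ord <- order(set$contig, set$start)
  lines <- sprintf("%s\t%d\t%d\ths_%d\t%.3f\t.\t%.4f",
                   set$contig[ord], set$start[ord], set$end[ord],
                   seq_along(ord), set$density[ord], set$z[ord])
  writeLines(lines, path)
  invisible(path)
}

#' Read hotspots from BED5+ written by [write_hotspots_bed()]
#' @param path BED file path.
#' @param label set label.
#' @export
read_hotspots_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stopf("hotspot BED not found: %s", path)
  if (file.size(path) == 0) {
    return(hotspot_set(data.frame(contig = character(), start = integer(),
                                  end = integer(), tag_count = integer(),
                                  density = numeric(), z = numeric()),
                       label = label))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 7) stopf("%s: expected 7 columns", path)
  hotspot_set(data.frame(contig = df[[1]],
                         start = as.integer(df[[2]]),
                         end = as.integer(df[[3]]),
                         tag_count = NA_integer_,
                         density = as.numeric(df[[5]]),
                         z = as.numeric(df[[7]]),
                         stringsAsFactors = FALSE),
              label = label)
}

#' Read gene models from the documented TSV format
#'
#' Tab-delimited with header `gene_id contig strand tss tts exons`, one row
#' per TSS record (multiple rows per gene id encode alternative TSSs). The
#' `exons` column holds comma-separated `start-end` pairs in 0-based
#' half-open coordinates. TSS is the 5' gene end: on + strand tss <= tts, on
#' - strand tss >= tts; rows violating that are rejected.
#'
#' @param path TSV path.
#' @return data.frame of gene models (class `gene_models`).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stopf("gene table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "contig", "strand", "tss", "tts", "exons")
  if (!all(need %in% names(df))) {
    stopf("gene table must have columns %s", paste(need, collapse = ", "))
  }
  df$tss <- as.integer(df$tss)
  df$tts <- as.integer(df$tts)
  bad <- which((df$strand == "+" & df$tss > df$tts) |
                 (df$strand == "-" & df$tss < df$tts) |
                 !df$strand %in% c("+", "-"))
  if (length(bad)) {
    stopf("gene table row %d: TSS/TTS inconsistent with strand", bad[1])
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to TSV
#' @param genes a `gene_models` data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  cols <- c("gene_id", "contig", "strand", "tss", "tts", "exons")
  utils::write.table(as.data.frame(genes)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Tab-delimited with header `gene_id transcripts_per_cell`.
#'
#' @param path TSV path.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "transcripts_per_cell")
  if (!all(need %in% names(df))) {
    stopf("expression table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$transcripts_per_cell < 0)) stopf("negative expression value")
  df
}

#' Write a per-gene expression table
#' @param expression data.frame with gene_id and transcripts_per_cell.
#' @param path output path.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression[, c("gene_id", "transcripts_per_cell")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse the exon column of a gene-model row
#'
#' @param exons character vector of comma-separated `start-end` blocks.
#' @return list of data.frames with columns start, end.
#' @export
parse_exons <- function(exons) {
  lapply(strsplit(exons, ","), function(blocks) {
    blocks <- blocks[nzchar(blocks)]
    if (!length(blocks)) {
      return(data.frame(start = integer(), end = integer()))
    }
    m <- do.call(rbind, strsplit(blocks, "-"))
    data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  })
}

#' Read a run configuration
#'
#' YAML file of flat keys; values override the defaults from
#' [default_config()].
#'
#' @param path YAML path.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg
}
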