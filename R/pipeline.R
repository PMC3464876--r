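# End-to-end orchestration: simulate -> callhotspots -> compare -> bias ->
# annotate, driven by a flat config, with a JSON run manifest recording
# seeds, outputs and summary numbers. Stages communicate through files in
# the output directory, so any stage can be re-run alone against an earlier
# run's outputs.

PIPELINE_STAGES <- c("simulate", "callhotspots", "compare", "bias", "annotate")

#' Default pipeline configuration
#'
#' A compact demo-scale setup (2 Mb genome, two enzymes, 1e5 fragments each)
#' that completes on one CPU in well under a minute per stage. Every value
#' can be overridden via [read_config()] or by editing the returned list.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "results/pipeline",
    stages = PIPELINE_STAGES,
    genome = list(n_contigs = 1L, contig_len = 2e6, gc_block_len = 20000,
                  gc_levels = c(0.35, 0.45, 0.55), n_cpg_islands = 20L),
    landscape = list(n_regions = 60L, meanlog = log(8), sdlog = 0.8,
                     promoter_fraction = 0.5, expression_coupling = 2),
    digestion = list(enzymes = c("benzonase", "dnase1"), n_fragments = 1e5,
                     min_len = 100L, max_len = 500L, tag_len = 36L,
                     mito_fraction = 0.05),
    hotspots = list(small_window = 250L, background_window = 200000L,
                    step = 50L, n_randomizations = 20L),
    bias_k = 10L,
    tss_flank = 3000L,
    profile_bin = 50L
  )
}

# deterministic per-stage seed: base seed offset by 1000 x the stage's
# position in the canonical stage order
stage_seed <- function(base_seed, stage) {
  (as.integer(base_seed) + 1000L * match(stage, PIPELINE_STAGES)) %% .Machine$integer.max
}

#' Run the configured pipeline stages
#'
#' Executes the stages listed in `config$stages` in canonical order. Stage
#' outputs are TSV/BED/FASTA files under `outdir`; a `manifest.json` records
#' the config snapshot, per-stage seeds, output checksums and summary
#' numbers. Identical config and seeds reproduce all outputs byte-for-byte.
#'
#' @param config configuration list ([default_config()] / [read_config()]).
#' @param outdir output directory; defaults to `config$outdir`.
#' @return the manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config = default_config(), outdir = config$outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(PIPELINE_STAGES, config$stages)
  path <- function(...) file.path(outdir, ...)
  summary <- list()
  enzymes <- config$digestion$enzymes

  for (stage in stages) {
    seed <- stage_seed(config$seed, stage)
    message(sprintf("[%s] seed=%d", stage, seed))
    if (stage == "simulate") {
      genome <- generate_genome(
        n_contigs = config$genome$n_contigs,
        contig_len = config$genome$contig_len,
        gc_block_len = config$genome$gc_block_len,
        gc_levels = config$genome$gc_levels,
        n_cpg_islands = config$genome$n_cpg_islands,
        seed = seed
      )
      write_fasta(genome, path("genome.fa"))
      utils::write.table(attr(genome, "cpg_islands"),
                         path("islands_planted.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sim <- generate_landscape(
        genome, n_regions = config$landscape$n_regions,
        intensity_law = list(meanlog = config$landscape$meanlog,
                             sdlog = config$landscape$sdlog),
        promoter_fraction = config$landscape$promoter_fraction,
        expression_coupling = config$landscape$expression_coupling,
        seed = seed + 1L
      )
      utils::write.table(sim$landscape$regions, path("regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_table(sim$genes, path("genes.tsv"))
      write_expression(sim$expression, path("expression.tsv"))
      for (i in seq_along(enzymes)) {
        lib <- simulate_digestion(
          genome, sim$landscape, preset_bias(enzymes[i]),
          n_fragments = config$digestion$n_fragments,
          fragment_model = list(min_len = config$digestion$min_len,
                                max_len = config$digestion$max_len),
          tag_len = config$digestion$tag_len,
          mito_fraction = config$digestion$mito_fraction,
          seed = seed + 10L + i
        )
        write_tags_bed(lib, path(sprintf("tags_%s.bed", enzymes[i])))
      }
      summary$n_regions <- nrow(sim$landscape$regions)
      summary$n_genes <- length(unique(sim$genes$gene_id))
    } else if (stage == "callhotspots") {
      gl <- genome_lengths(read_fasta(path("genome.fa")))
      hp <- do.call(hotspot_params, config$hotspots)
      for (i in seq_along(enzymes)) {
        enz <- enzymes[i]
        lib <- read_tags_bed(path(sprintf("tags_%s.bed", enz)), gl,
                             label = enz)
        hs <- call_hotspots(lib, gl, hp, seed = seed + i)
        write_hotspots_bed(hs, path(sprintf("hotspots_%s.bed", enz)))
        p <- attr(hs, "params")
        summary[[paste0("hotspots_", enz)]] <- nrow(hs)
        summary[[paste0("z_threshold_", enz)]] <- p$z_threshold
        summary[[paste0("mito_fraction_", enz)]] <- p$mito_fraction
        message(sprintf("  %s: %d hotspots (z >= %.2f, mode cutoff %.2f, mito %.3f)",
                        enz, nrow(hs), p$z_threshold,
                        if (is.null(p$mode_cutoff)) NA else p$mode_cutoff,
                        p$mito_fraction))
      }
    } else if (stage == "compare") {
      gl <- genome_lengths(read_fasta(path("genome.fa")))
      sets <- lapply(stats::setNames(enzymes, enzymes), function(enz) {
        read_hotspots_bed(path(sprintf("hotspots_%s.bed", enz)), label = enz)
      })
      ov <- overlap_summary(sets)
      utils::write.table(ov$patterns, path("overlap_patterns.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (enz in enzymes) {
        qo <- quartile_overlap(sets[[enz]],
                               sets[names(sets) != enz])
        utils::write.table(qo, path(sprintf("quartile_overlap_%s.tsv", enz)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      um <- union_merge(sets)
      libs <- lapply(stats::setNames(enzymes, enzymes), function(enz) {
        read_tags_bed(path(sprintf("tags_%s.bed", enz)), gl, label = enz)
      })
      if (length(enzymes) >= 2 && nrow(um) >= 2) {
        summary$union_density_r <- density_correlation(libs[[1]], libs[[2]],
                                                       um)
      }
      summary$union_hotspots <- nrow(um)
      shared <- um[[enzymes[1]]]
      for (enz in enzymes[-1]) shared <- shared & um[[enz]]
      summary$shared_percent <- 100 * mean(shared)
    } else if (stage == "bias") {
      genome <- read_fasta(path("genome.fa"))
      gl <- genome_lengths(genome)
      for (enz in enzymes) {
        lib <- read_tags_bed(path(sprintf("tags_%s.bed", enz)), gl,
                             label = enz)
        prof <- cut_site_base_frequency(lib, genome, k = config$bias_k)
        df <- data.frame(offset = prof$offsets, t(prof$freq))
        utils::write.table(df, path(sprintf("base_frequency_%s.tsv", enz)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary[[paste0("modal_base_", enz)]] <-
          rownames(prof$freq)[which.max(prof$freq[, as.character(0)])]
      }
      islands <- find_cpg_islands(genome)
      utils::write.table(islands, path("cpg_islands.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sets <- lapply(stats::setNames(enzymes, enzymes), function(enz) {
        read_hotspots_bed(path(sprintf("hotspots_%s.bed", enz)), label = enz)
      })
      for (enz in enzymes) {
        if (nrow(sets[[enz]]) > 0) {
          summary[[paste0("cpg_overlap_", enz)]] <-
            cpg_overlap_fraction(sets[[enz]], islands)
        }
      }
    } else if (stage == "annotate") {
      gl <- genome_lengths(read_fasta(path("genome.fa")))
      genes <- read_gene_table(path("genes.tsv"))
      expr <- read_expression(path("expression.tsv"))
      sets <- lapply(stats::setNames(enzymes, enzymes), function(enz) {
        read_hotspots_bed(path(sprintf("hotspots_%s.bed", enz)), label = enz)
      })
      for (enz in enzymes) {
        fd <- feature_distribution(sets[[enz]], genes)
        utils::write.table(fd, path(sprintf("feature_distribution_%s.tsv",
                                            enz)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      binning <- bin_expression(expr, "log2")
      occ <- tss_occupancy(genes, sets, binning)
      utils::write.table(occ, path("tss_occupancy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      for (enz in enzymes) {
        lib <- read_tags_bed(path(sprintf("tags_%s.bed", enz)), gl,
                             label = enz)
        prof <- aggregate_density(genes, lib, flank = config$tss_flank,
                                  bin_width = config$profile_bin,
                                  anchor_mode = "tss")
        utils::write.table(prof, path(sprintf("tss_profile_%s.tsv", enz)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summary$occupancy_top_bin <- occ$occupancy[nrow(occ)]
      summary$occupancy_nd <- occ$occupancy[1]
    }
  }

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    tool = "tachseq",
    version = as.character(utils::packageVersion("tachseq")),
    config = config,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) stage_seed(config$seed, s)), stages),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(outdir, files)))), files),
    summary = summary
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
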