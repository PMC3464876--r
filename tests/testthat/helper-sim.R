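# Shared simulation fixtures, built once per test run and cached. Seeds are
# fixed so every fixture is deterministic. The scenario parameters are the
# package defaults documented in the methods vignette.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small world for module-level tests: 2 Mb, quick to simulate
small_world <- function() {
  fixture("small_world", {
    genome <- generate_genome(n_contigs = 1, contig_len = 2e6,
                              n_cpg_islands = 10, seed = 101)
    sim <- generate_landscape(genome, n_regions = 60, seed = 102)
    lib <- simulate_digestion(genome, sim$landscape, preset_bias("uniform"),
                              1e5, mito_fraction = 0.05, seed = 103)
    list(genome = genome, gl = genome_lengths(genome), sim = sim, lib = lib)
  })
}

# the default study-scale simulation: 10 Mb, 200 planted regions, log-normal
# intensities, 1e6 fragments under uniform cut bias
default_sim <- function() {
  fixture("default_sim", {
    genome <- generate_genome(n_contigs = 2, contig_len = 5e6,
                              n_cpg_islands = 100, seed = 1)
    sim <- generate_landscape(genome, n_regions = 200, seed = 2)
    lib <- simulate_digestion(genome, sim$landscape, preset_bias("uniform"),
                              1e6, seed = 3, label = "uniform_1M")
    list(genome = genome, gl = genome_lengths(genome), sim = sim, lib = lib)
  })
}

default_hotspots <- function() {
  fixture("default_hotspots", {
    d <- default_sim()
    call_hotspots(d$lib, d$gl, seed = 4)
  })
}

# companion libraries from the same landscape: a 4x-lower-depth library and
# a full-depth replicate of the default library
depth_libraries <- function() {
  fixture("depth_libraries", {
    d <- default_sim()
    list(
      quarter = simulate_digestion(d$genome, d$sim$landscape,
                                   preset_bias("uniform"), 2.5e5, seed = 5,
                                   label = "uniform_250k"),
      rep2 = simulate_digestion(d$genome, d$sim$landscape,
                                preset_bias("uniform"), 1e6, seed = 6,
                                label = "uniform_1M_b")
    )
  })
}

# mixed-GC world: isochore-like 30/50/70% GC blocks, many weak regions, the
# same landscape digested with the G/C-preferring and T-preferring enzymes
mixedgc_sim <- function() {
  fixture("mixedgc_sim", {
    genome <- generate_genome(n_contigs = 2, contig_len = 5e6,
                              gc_levels = c(0.3, 0.5, 0.7),
                              n_cpg_islands = 60, seed = 31)
    sim <- generate_landscape(genome, n_regions = 300,
                              intensity_law = list(meanlog = log(3),
                                                   sdlog = 0.7),
                              seed = 32)
    benz <- simulate_digestion(genome, sim$landscape,
                               preset_bias("benzonase"), 3e5, seed = 33,
                               label = "benzonase")
    dnase <- simulate_digestion(genome, sim$landscape, preset_bias("dnase1"),
                                3e5, seed = 34, label = "dnase1")
    gl <- genome_lengths(genome)
    list(genome = genome, gl = gl, sim = sim,
         benz = benz, dnase = dnase,
         hs_benz = call_hotspots(benz, gl, seed = 35),
         hs_dnase = call_hotspots(dnase, gl, seed = 36))
  })
}

# expression-coupled world on the default genome: many regions under an
# intensity law kept clear of the baseline clamp (so every expressed gene is
# genuinely more accessible than background) and wide enough that per-bin
# occupancy is graded rather than saturated
coupled_sim <- function() {
  fixture("coupled_sim", {
    d <- default_sim()
    sim <- generate_landscape(d$genome, n_regions = 1200,
                              intensity_law = list(meanlog = log(5),
                                                   sdlog = 0.8),
                              promoter_fraction = 0.75,
                              expression_coupling = 1, seed = 21)
    lib <- simulate_digestion(d$genome, sim$landscape,
                              preset_bias("benzonase"), 1e6, seed = 22,
                              label = "benzonase_coupled")
    list(genome = d$genome, gl = d$gl, sim = sim, lib = lib,
         hs = call_hotspots(lib, d$gl, seed = 23))
  })
}
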