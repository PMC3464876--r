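---
title: "Methods: simulating and analysing nuclease-digestion accessibility data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing nuclease-digestion accessibility data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tachseq` analyses chromatin accessibility data of the tag-library kind:
chromatin is partially digested with an endonuclease (DNase I in classical
DNase-seq; robust enzymes such as Benzonase or Cyanase when working from
frozen tissue), released fragments of roughly 100–500 bp are size-selected
and sequenced single-ended, and each aligned tag's 5' end marks one cleavage
event. Everything downstream of alignment is in scope: hotspot calling,
cross-enzyme comparison, cut-site sequence-bias profiling and
regulatory-feature annotation. Wet-lab chemistry and read alignment are not;
the pipeline consumes aligned tags in BED form.

Because deposited sequencing libraries of 20–30 million tags are not a
desk-scale test substrate, the package carries a first-class simulator that
generates genomes, accessibility landscapes and digestion libraries with
known ground truth. Every analysis stage is validated against that truth or
against brute-force recomputation.

# The hotspot model

Cut sites are modelled as locally Poisson with an unknown, slowly varying
background rate. For each small window of $w$ bp (default 250) stepped by
$s$ bp (default 50), let $n$ be the number of cut sites in the window and
$N$ the number in a centred background window of $B$ bp (default 200,000),
clipped at contig edges. Under the null that the window is ordinary
background, $n \sim \mathrm{Binomial}(N, p)$ with $p = w / B_\mathrm{eff}$,
where $B_\mathrm{eff}$ is the clipped background length, and the score is
the normal approximation

$$ z = \frac{n - Np}{\sqrt{Np(1-p)}}. $$

Windows with $N = 0$ carry no information and are skipped. Clipping with
recomputed $p$ matters here because synthetic contigs are often much shorter
than the 200 kb background.

**Empirical FDR-0 threshold.** The score cutoff is not parametric: the same
number of tags is placed uniformly over the (nuclear) genome, the scan is
repeated (20 placements by default), and the threshold is the maximum
random $z$ plus machine epsilon — the smallest cutoff at which the expected
number of passing windows under the random model is zero. This is a literal
reading of calling at 0% empirical FDR.

**Merging and trimming.** Passing windows separated by gaps of at most $w$
bp are merged; each merged interval is trimmed to the span of the cut sites
it actually contains. The merge gap and the trimming convention are
deliberately simple and deterministic, so an exhaustive per-window oracle
can recompute them exactly; published variants of the method differ here and
both scales are config-exposed.

**Density and the mode filter.** Each hotspot records its tag count, its
density in tags per kb per million library tags (depth-invariant, so
cross-library scatter comparisons are meaningful), and its maximal window
$z$. Finally a histogram of $\log_{10}$ density with bin width 0.1 is
built, the modal bin located, and hotspots below the modal bin's lower edge
discarded. Densities span decades, which is why the mode is taken on the
log scale — linear binning would place the mode in the smallest bin. A
single-hotspot set is returned unchanged. Mitochondrial tags (contig
`chrM`) are counted, reported, and excluded before calling, since
frozen-tissue digestion protocols yield an appreciable mitochondrial
fraction that would otherwise distort the background model.

# The simulator

The generative model is intentionally the simplest one that carries the
statistical structure the analyses assume:

* **Genome.** Nuclear contigs are i.i.d. bases in blocks (default 20 kb)
  whose GC level is drawn per block from a configurable set, giving
  isochore-like composition variation. CpG islands (500–1500 bp, ~70% GC,
  CpG observed/expected ≈ 1) are planted at recorded positions. A 16 kb
  uniform `chrM` contig supports mitochondrial-fraction reporting without
  modelling organelle biology. Background sequence is *not* CpG-depleted —
  a known difference from mammalian genomes that makes the
  Gardiner–Garden–Frommer island caller liberal on near-50%-GC background;
  island analyses on simulated data should therefore be read
  comparatively, not as absolute island counts.
* **Landscape.** Accessible regions (default 200–1000 bp wide) are placed
  uniformly and non-overlapping with log-normal cut-rate intensities,
  clamped below at the baseline 1. A configurable fraction are "promoters":
  each spawns a gene whose TSS lies inside the region and whose expression
  is `coupling × intensity × exp(ε)`, `ε ~ N(0, 0.5)`; an equal number of
  silent genes (zero transcripts) is placed in unplanted sequence, with a
  margin (default 1500 bp) between a silent TSS and any region so that
  silent promoters sit in genuinely closed chromatin, clear of the
  fragment-length smear of tags around planted regions. This is the
  machinery behind every expression-coupling analysis.
* **Digestion.** Per fragment, a first cut is drawn with probability
  proportional to `landscape rate × enzyme base weight at the cut base`; a
  second cut is drawn 100–500 bp downstream with the same weighting read on
  the strand being cut (reverse-complement base for the downstream cut); a
  fair coin picks the sequenced end and a 36 bp tag is emitted inward from
  that cut, stranded so its 5' end is the cut site. One tag per fragment
  mirrors single-end sequencing. Enzyme bias acts only at the cut base
  (offset 0): the observable it must reproduce is the single-position 5'
  base frequency, and positional cleavage matrices are an explicit
  non-goal. The preset weights (Benzonase = Cyanase: A .15, C .30, G .40,
  T .15; DNase I: A .20, C .15, G .15, T .50; uniform: .25 each) encode
  only the direction of the published preferences — G/C for
  Benzonase/Cyanase, T for DNase I; the magnitudes are calibration choices
  and are fully configurable.

All generators are deterministic under a seed, with the caller's RNG state
restored afterwards.

# Comparison, bias and annotation conventions

* **Overlap** between hotspots is ≥ 1 bp, the simplest defensible reading
  of "identified by both"; Venn-style counting is over merged union
  intervals rather than per-source counts, which would double-count split
  or merged regions.
* **Density correlations** are Pearson on `log10(density + 0.1)`. Hotspot
  densities span decades; a linear-scale coefficient would be dominated by
  a handful of the strongest regions. The pseudocount keeps empty regions
  finite and is small against any called hotspot's density.
* **Quartile parsing** sorts by density descending with ties broken by
  (contig, start), splitting into four near-equal groups, extras to the
  most intense quartiles — deterministic under total ties.
* **Cut-site windows** are read strand-relatively: offset 0 is the first
  sequenced base, negative offsets upstream of the cut; offsets that fall
  off the contig are dropped from that offset's denominator only.
* **CpG islands** use the Gardiner–Garden–Frommer thresholds (every 200 bp
  window with GC ≥ 50% and observed/expected CpG ≥ 0.6, merged runs ≥ 200
  bp). The thresholds are config-exposed and a user-supplied island BED can
  bypass the caller.
* **Feature classification** is by hotspot midpoint with fixed priority
  promoter > exon > intron > downstream > distal (promoter = 2 kb upstream
  of a TSS, downstream = 2 kb past the TTS, strand-respecting). Midpoint +
  priority resolves multi-category overlaps deterministically.
* **Expression bins**: the eight-bin scheme uses unit-log2 bins over
  detected genes with configurable edges (default boundaries at log2 =
  −1…5, top bin open) and a separate "nd" class for undetected genes; the
  decile scheme ranks by expression descending with ties broken by gene id
  and undetected genes last. A gene with several TSS records counts as
  occupied when any TSS lies inside a hotspot (point-in-interval).
* **Aggregation profiles** tally cut sites into offset bins around anchor
  midpoints (or strand-oriented TSSs), averaged per anchor and normalized
  to tags per bp per million; heatmap rows are the same quantity before
  averaging and are left unsmoothed.

# Validation scenarios and problem sizes

The test suite builds its worlds at sizes chosen to make sampling noise
small against the effects being asserted while staying desk-scale:

* *Default world*: 10 Mb over two contigs, 200 planted regions with
  log-normal(log 8, 0.8) intensities, 10^6 fragments under uniform bias.
  Used for planted-region recovery (sensitivity on the top intensity half,
  precision of calls) and, with 4×-reduced-depth and replicate libraries,
  for depth-robustness correlations.
* *Mixed-GC world*: GC levels {0.3, 0.5, 0.7}, 300 regions with weak
  log-normal(log 3, 0.7) intensities, 3 × 10^5 fragments per enzyme. Weak
  regions sit near the detection boundary, so the G/C- versus T-preferring
  presets tip marginal regions in their favoured composition — the
  mechanism behind the GC ordering of enzyme-unique versus common hotspots
  and the quartile-resolved uniqueness gradient.
* *Coupled world*: 1200 regions with log-normal(log 5, 0.8) intensities,
  75% carrying genes (900 expressed, 900 silent), coupling 1. The law is
  wide enough that TSS occupancy is graded rather than saturated, yet puts
  almost no mass at the baseline clamp, so every expressed gene is
  genuinely more accessible than background — the structure the coupling
  analyses assert. The large gene count keeps per-bin estimates stable;
  occupancy and mean TSS density monotonicity are asserted over expression
  bins holding at least 10 genes, since fractions over a handful of genes
  are dominated by single-gene noise.
* Oracle-equivalence checks (scan, caller, CpG islands, base counting,
  union membership) run on instances of at most 10 kb where exhaustive
  loops are feasible.

Uniform-placement soundness uses 20 independent 10^5-tag libraries on 10 Mb
and asserts a mean of ≤ 0.05 hotspots per library. Note the discreteness of
the scan helps here: a uniform library's maximal window score usually ties,
rather than exceeds, the randomization maximum, so the FDR-0 threshold
rejects it.

# Numerical choices and degenerate inputs

* Binomial z rather than an exact tail probability: with the default scales
  $Np$ is a few tags and the normal approximation is the scan's standard
  form; the FDR threshold is empirical anyway, so only the ranking of
  windows matters.
* The FDR-0 threshold adds a relative machine epsilon to the random
  maximum, making "strictly above every random window" exact under
  floating-point equality of tied scores.
* The mode filter compares log densities with a 1e-9 guard so hotspots
  sitting exactly on a bin edge are kept.
* Degenerate inputs have defined behaviour: empty libraries error in the
  caller ("no tags"); a single hotspot passes the mode filter unchanged;
  zero-variance density vectors error in the correlation ("degenerate");
  unstranded tags are rejected at parse time because the cut-site
  definition needs a strand; all-N intervals yield NaN GC and are flagged
  by exclusion from denominators.
* Pipeline stage seeds derive from the global seed by a fixed offset per
  stage (base + 1000 × stage index), so a stage re-run alone reproduces its
  original output.

# Known limitations

The simulator omits sequencing error, paired-end fragments, positional
(multi-offset) cleavage preferences, chromatin higher-order structure and
background CpG depletion. Passing tests therefore demonstrate that the
analysis stack recovers the structure this generative model encodes —
planted accessibility, depth invariance, single-base enzyme bias,
expression coupling — not that it is robust to every artefact of real
libraries. Replicate-aware reproducibility statistics, footprint-resolution
analysis and broad-domain calling are out of scope.
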