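# tachseq

Chromatin accessibility mapping from nuclease-digestion tag libraries.

Partial digestion of chromatin with an endonuclease — DNase I on purified
nuclei, or robust enzymes such as Benzonase and Cyanase applied directly to
pulverized frozen tissue — releases short DNA fragments preferentially from
open, regulatory chromatin. After size selection (100–500 bp) and single-end
sequencing, each aligned tag's 5' end marks one cleavage event, and regions
of locally enriched cut density ("hotspots") mark accessible chromatin.
`tachseq` implements the computational side of such an experiment for
analysts working with tag libraries in BED form, together with a synthetic
digestion simulator that provides ground truth for validating every stage.

## The statistic at the core

For each small window of $w$ bp (default 250, step 50) inside a centred
local background of $B$ bp (default 200 kb, clipped at contig edges), with
$n$ of the background's $N$ cut sites falling in the window and
$p = w/B_\mathrm{eff}$, the scan score is

$$z = \frac{n - Np}{\sqrt{Np(1-p)}}.$$

The calling threshold is empirical, at 0% FDR: the library's tags are placed
uniformly over the genome 20 times, each placement is scanned, and the
threshold is the maximum random $z$ plus machine epsilon. Passing windows
are merged (gap ≤ $w$), trimmed to their cut-site span, scored with a
depth-invariant density (tags/kb/million tags), and filtered at the mode of
the log₁₀-density histogram (bin 0.1). Mitochondrial tags are reported
separately and excluded before calling.

Around the caller sit modules for cross-library comparison (union/Venn
membership over merged intervals, density-quartile parsing, log-density
correlations), cut-site sequence bias (strand-oriented 5' base frequencies,
GC content and profiles, Gardiner–Garden–Frommer CpG islands) and feature
annotation (promoter/exon/intron/downstream/distal classification, TSS
occupancy by expression bin, metagene aggregation profiles and heatmap
matrices).

## Worked example

Simulate a 2 Mb genome with planted accessible regions, digest it, and call
hotspots:

```r
library(tachseq)

genome <- generate_genome(n_contigs = 1, contig_len = 2e6,
                          n_cpg_islands = 10, seed = 7)
sim <- generate_landscape(genome, n_regions = 60, seed = 8)
lib <- simulate_digestion(genome, sim$landscape, preset_bias("benzonase"),
                          n_fragments = 1e5, mito_fraction = 0.05, seed = 9)
lib
#> tag_library 'benzonase': 100000 tags on 2 contig(s)

hs <- call_hotspots(lib, genome_lengths(genome), seed = 10)
nrow(hs)
#> [1] 46
attr(hs, "params")$z_threshold
#> [1] 5.808987
mito_fraction(lib)
#> [1] 0.0504

prof <- cut_site_base_frequency(lib, genome, k = 5)
round(prof$freq[, "0"], 3)
#>     A     C     G     T
#> 0.176 0.281 0.369 0.175
```

46 hotspots are called above the randomization threshold (z ≥ 5.81); the
library's 5% mitochondrial tags are reported and excluded. The 5' base
frequency at the cut site recovers the simulated enzyme's G/C preference
(modal base G at 37%, against a genome-wide G fraction near 25%) — the
signature that distinguishes Benzonase/Cyanase from the T-preferring
DNase I in real libraries.

The numbered scripts under `analysis/` run the full study narrative —
simulate three enzymes, call hotspots, compare enzymes, profile sequence
bias, relate accessibility at TSSs to expression — writing tables and
figures under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_hotspots.R
Rscript analysis/03_compare_enzymes.R
Rscript analysis/04_sequence_bias.R
Rscript analysis/05_tss_expression.R
```

`run_pipeline()` performs the same stages from a single (YAML-configurable)
config with a JSON manifest; identical config and seed reproduce every
output byte for byte.

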