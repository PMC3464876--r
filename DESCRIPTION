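Package: tachseq
Title: Simulation and Analysis of Nuclease-Digestion Chromatin Accessibility Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping chromatin accessibility from nuclease-digestion
    tag libraries (TACh/DNase-seq style data). Implements a binomial
    local-background scan statistic with an empirical FDR-0 threshold and a
    tag-density mode filter for hotspot calling; cross-enzyme hotspot
    comparison (union/Venn overlap, density-quartile parsing, depth-invariant
    density correlations); nuclease cut-site sequence-bias profiling and CpG
    island analysis; and regulatory-feature annotation (promoter/exon/intron
    classification, TSS occupancy by expression bin, metagene aggregation
    profiles). A synthetic digestion simulator with enzyme-specific cut-site
    base preferences, fragment size selection and expression-coupled planted
    accessible regions provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
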