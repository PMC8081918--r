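Package: repairspot
Title: Super Hotspots and Super Coldspots of Nucleotide Excision Repair from
    XR-seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genomic sites of earliest ("super hotspot") and
    latest ("super coldspot") nucleotide excision repair from time-course
    XR-seq read data. Implements post-alignment read filtering, fixed-depth
    downsampling, 50-bp strand-specific binning with blacklist masking, a
    replicate-wise threshold caller, and a robust Poisson log-linear null
    model (library size x bin propensity x pyrimidine-content bias) for
    per-bin enrichment testing. Downstream characterization covers
    gene-level transcribed/nontranscribed-strand repair ratios and PCA
    repair trajectories, single-nucleotide damage hotspot calling from
    Damage-seq-style reads, bootstrap interval-overlap enrichment against
    regulatory and 3D-genome annotations, and damage-centered nucleotide
    frequency profiles. A first-class synthetic-data module generates
    miniature genomes, reads, genes, and annotations with planted structure
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
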