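Package: intercds
Title: Inter-CDS Region Length Distributions and Minimal Regulatory Space
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extraction and orientation-classification of inter-CDS regions
    (the DNA between the ORF boundaries of adjacent protein-coding genes),
    ortholog-based assignment of region age from gene-neighbourhood
    conservation against a rooted species tree, length-distribution
    statistics (log-normal and two-Gaussian fits with a nested F-test,
    lower-limit estimation, orientation-composition tests, cross-species
    summaries), and a neutral distance-dependent rearrangement simulator
    that predicts the length distribution of ancestral regions from the
    total distribution by length-weighted removal.  Ships a synthetic
    multi-species clade generator so the whole pipeline is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    S4Vectors,
    graphics,
    IRanges,
    jsonlite,
    minpack.lm,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
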