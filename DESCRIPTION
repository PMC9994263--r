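Package: chorscar
Title: Histone Modification Restoration Kinetics and Sister-Chromatid
    Partition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of histone H2A-H2B modification dynamics
    across DNA replication. Implements spike-in (reference-adjusted reads
    per million, RRPM) normalization of ChOR-seq chase time courses, a
    first-order restoration kinetics model with derived t90 and recycled
    fraction, fold-change restoration categories with replicate agreement,
    consensus peak and decorated-gene interval algebra, and SCAR-seq/OK-seq
    strand analysis: partition and replication fork directionality scores,
    uniform-blur smoothing, input correction, initiation-zone edge
    detection, meta-profiles, and Wilcoxon signed-rank asymmetry tests.
    A seeded synthetic-data generator emulates the signal structure of
    these assays so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
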