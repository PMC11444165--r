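Package: enhancermap
Title: Single-Cell Histone-Mark Enhancer Maps: QC, Clustering, and
    Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-cell histone-modification
    (H3K27ac CUT&Tag/CoBATCH-style) profiles of heterogeneous cell
    populations. Builds per-cell quality metrics and binary peak-by-cell
    detection matrices from genomic fragment files, embeds and clusters
    cells with TF-IDF/LSI and a resolution cluster tree, calls
    cluster-specific enhancer peaks, scores gene activity from enhancer
    signal in gene-proximal windows, tests GWAS variant enrichment in
    cell-type-specific enhancers with an exact binomial model, infers
    distance-bounded cis-co-accessibility networks from aggregated
    meta-cells, scores per-cell motif deviations against matched
    background peaks, assembles transcription-factor target-gene
    networks, and performs neighbourhood-level differential abundance
    between conditions. Ships a seedable synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
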