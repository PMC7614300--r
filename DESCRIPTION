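Package: regland
Title: Regulatory Landscape Analysis for Cell-Type-Resolved Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of cell-type-resolved ATAC-seq experiments in
    developing neural progenitors: consensus-peak filtering and normalization,
    simplified negative-binomial differential accessibility testing with the
    standard pairwise comparison plan, two-stage k-means/hierarchical clustering
    of element dynamics with semantic cluster labeling and regulatory-regime
    classification, transcription-factor footprint scoring with motif-archetype
    grouping and RNA-correlation ranking of candidate driver factors,
    interval-overlap enrichment against ChIP peak sets, and quantification of
    lineage-traced cell classes from multi-channel section images. A synthetic
    data generator plants known ground truth (accessibility patterns, regimes,
    driver factors, nucleus classes) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    EBImage,
    mclust,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
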