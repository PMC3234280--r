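Package: tsoscan
Title: Integrative Copy Number, Methylation and Expression Screening for
    Tumor Suppressor and Oncogene Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Nominates tumor-suppressor-like and oncogene-like genes in a
    tumor cohort by integrating segmented DNA copy number (CBS/SEG tables),
    promoter methylation (MOMA-style GeoMeanRatio scores or Infinium beta
    values) and log2 expression. Implements segment-to-gene assignment under
    strict full-containment and marker-count rules, near-zero seg.mean
    trimming, CNV state classification, cross-platform deletion-threshold
    calibration, quantile normalization, CNV-stratified Mann-Whitney
    expression screens with Benjamini-Hochberg FDR control, per-gene
    correlation screens, a quadrant feature classifier combining CNV state
    with expression-ratio and methylation quantiles, two-sample Hotelling
    T-squared significance against normals, hypergeometric gene-set
    enrichment, and a synthetic multi-omics cohort simulator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
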