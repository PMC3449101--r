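Package: swatcna
Title: Sliding-Window Adaptive-Threshold Detection of Recurrent Copy Number
    Aberrations from Array CGH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies recurrent copy number aberration (CNA) regions of
    interest from array comparative genomic hybridisation (aCGH) cohorts.
    Takes probe-level log2 ratios plus per-sample segment calls from any
    external segmentation algorithm, applies a five-point probe
    classification, scores sliding probe windows by cross-sample recurrence
    (probe window scores, PWS), gates each chromosome with adaptive
    thresholds so that about 10 percent of it is flagged, and extracts
    contiguous and minimum regions of interest (CRIs and MRIs). Detected
    regions are prioritised by a permutation-based amplitude significance
    test and by gene-density weighting, consolidated across segmentation
    methods into a consensus list, and used for unsupervised sample
    clustering. Includes a synthetic-data module (toy fixture, planted-CNA
    cohorts, a naive reference segmenter) and web-style HTML reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    patchwork,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    grDevices,
    tools
Suggests:
    ape,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
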