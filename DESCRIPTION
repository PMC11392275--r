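Package: zdosage
Title: Germline Z-Chromosome Dosage and Accessibility Analysis for
    Single-Nucleus Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects dosage compensation and meiotic sex-chromosome
    repression in ZW germline cells from paired single-nucleus RNA and
    ATAC data. Computes per-cell ratios of mean expression in a
    sex-chromosome stratum (e.g. the differentiated S0 region of the Z)
    to mean autosomal expression, anchors them with a somatic-median
    adjustment, and classifies each cell into dosage-compensated,
    lack-of-compensation and repressed zones under fixed or
    percentile-based cutoffs with chi-square enrichment tests. Adds
    gene-window sparsity controls, pseudo-bulk ATAC fragment counting in
    500-kb compartment-labelled windows with median-log2 adjustment,
    spliced/unspliced transcriptional-shutdown metrics, and a paired
    snRNA/snATAC simulator with known per-cell dosage regimes so every
    stage is verifiable against generative ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
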