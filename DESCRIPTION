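Package: molmap
Title: Spatial Mapping and Injury Response of Mature Oligodendrocyte Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification machinery for mapping transcriptionally defined
    mature oligodendrocyte (MOL) populations across tissue regions and injury
    conditions. Implements in situ sequencing barcode decoding with per-cycle
    quality scores, watershed nuclei segmentation with label expansion and
    spot-to-cell assignment, marker-cutoff cell typing for RNAscope puncta and
    ISS read counts, regional composition statistics with two-way ANOVA and
    Sidak-corrected comparisons, single-cell QC filtering, Wilcoxon
    differential expression with 2D-volcano construction and pathway
    embedding, and an iterative Moran's I manifold feature filter with
    hierarchical subclustering. Ships a synthetic-data generator that emulates
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    EBImage,
    tiff,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
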