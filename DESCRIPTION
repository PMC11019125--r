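Package: epiAgeClock
Title: Epigenetic Age Clocks from Chromatin Accessibility and DNA
    Methylation in Companion Dogs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates elastic-net epigenetic age clocks from
    chromatin-accessibility (ATAC-seq) peak counts and reduced-representation
    bisulfite sequencing (RRBS) CpG methylation fractions in peripheral blood
    mononuclear cells of companion dogs. Provides a synthetic-cohort generator
    with known ground truth, consensus-peak merging and coverage filters,
    CpG-site depth and intermediate-methylation filters, per-feature
    ordinary-least-squares age association with covariates and
    Benjamini-Hochberg adjustment, chromatin-state enrichment by Fisher's
    exact test, a coordinate-descent elastic-net solver with nested
    leave-one-out cross-validation and meta-features, and residual-age
    (age-acceleration) evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
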