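Package: vasculonet
Title: Co-Expression Network Analysis of the Brain Vascular Proteome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-batch tandem-mass-tag (TMT)
    proteomic studies of isolated cerebrovasculature with paired bulk
    tissue: iterative two-way median-polish batch correction against
    pooled global internal standards (GIS), cell-type marker scoring and
    fractionation outlier detection, bootstrap covariate regression with
    protected diagnosis effects, signed biweight-midcorrelation /
    topological-overlap co-expression module discovery with iterative
    kME-based reassignment, permutation Zsummary module preservation,
    module-trait and group differential statistics, and cell-type,
    GWAS-risk and biofluid overrepresentation analyses. Includes a
    synthetic cohort generator so every stage is testable without access
    to restricted patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
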