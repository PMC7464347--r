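Package: mrdeval
Title: Minimal Residual Disease Key Metrics and Assay Concordance in
    Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating bone-marrow minimal residual disease (MRD)
    measurements in multiple myeloma obtained by immunoglobulin
    next-generation sequencing (NGS) and EuroFlow-style multicolor flow
    cytometry (MFC). Computes sample-specific key metrics (tumor load,
    limit of detection, limit of quantification), assigns MRD status at a
    chosen cut-off via an explicit six-rule decision algorithm, and provides
    cohort-level analytics: cut-off sweeps, paired NGS/MFC concordance with
    Cohen's kappa, response-stratified MRD rates, and tumor-load
    correlation with outlier handling. A seeded generator produces
    synthetic paired cohorts with realistic cell-count and tumor-load
    distributions so every stage of the pipeline can be exercised without
    access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
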