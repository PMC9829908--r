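Package: microshift
Title: Transcriptome-Shift, Gene-Module and Microglial Morphometry Analysis
    for CSF1R-Inhibitor Tauopathy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies treatment-induced transcriptome shifts along a
    transgenic-versus-wild-type disease axis using partial least squares
    (PLS) regression, out-of-fit projection, Mahalanobis population-vector
    distances and vector angles; discovers dose- and sex-driven gene modules
    via variable importance in projection (VIP); clusters cell-type-specific
    genes with Louvain community detection on Pearson correlation networks;
    renormalizes depleted-cell expression with cell-type housekeeping genes
    to estimate per-surviving-cell ("resilient") profiles; computes composite
    behavioral and pathology scores (PCA tau score, home-cage activity score,
    comparative-CT fold change); and measures microglial skeleton
    morphometry and density-by-distance from pathology deposits. Includes a
    fully seeded synthetic cohort, reference-transcriptome, score-table and
    cell-image generator with planted ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
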