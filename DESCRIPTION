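Package: nodnet
Title: Time-Series Gene Co-Expression Network Analysis for Nodulation Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering temporally regulated biomarkers
    from inoculated-versus-control RNA-seq time courses. Starting from a gene
    expression matrix, the pipeline performs per-time-point negative-binomial
    differential expression, builds a condition-aware gene co-expression
    network with Gaussian-mixture sample clustering, selects the correlation
    significance threshold by random matrix theory (eigenvalue spacing
    statistics), detects overlapping link-community modules by single-linkage
    clustering of edge similarities cut at maximum partition density, overlays
    per-time-point differentially expressed genes to call modules composed
    entirely of same-direction DEGs, and runs Fisher's-exact functional
    enrichment. A synthetic-data generator with planted co-expression modules
    and planted differential expression makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    MASS,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
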