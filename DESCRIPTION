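Package: retinet
Title: Disease-Gene Network Construction and Hub Analysis for Retinal
    Disease Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds disease-gene, disease-phenotype and protein-disease
    networks from the relational tables of a compiled retinal-disease
    database, computes a topological-coefficient and centrality battery
    (radiality, betweenness, centroid value), fits power-law models to
    degree distributions, ranks and classifies hub genes, and quantifies
    network disaggregation after targeted node removal.  A seeded
    synthetic database generator with preferential-attachment
    disease-gene links supports end-to-end testing without any database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
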