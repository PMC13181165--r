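Package: bimiss
Title: Bipartite Network Analysis of Structured Missingness in Nominal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents a pair of nominal variables as a weighted bipartite
    network and treats the arrangement of missing edge weights as a signal in
    its own right. Builds incidence matrices from long-format tables,
    quantifies how missing cells are organised (matrix packing, the
    Atmar-Patterson nestedness temperature, Newman modularity, a runs-based
    permutation test on label sequences with Benjamini-Hochberg correction),
    extracts large complete submatrices by a greedy peeling heuristic,
    projects the bipartite network onto either node set and clusters the
    projections with seven community-detection algorithms, imputes missing
    edge weights (mean, median, iterative correspondence analysis,
    regularised alternating least squares), and scores each imputation by
    how well clustering of the imputed network reproduces the clustering of
    the complete-submatrix benchmark via pair-counting indices. Includes a
    generator for synthetic bipartite matrices with planted modular, nested
    or random structure and MCAR, block or value-threshold missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
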