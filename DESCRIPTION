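Package: paretoscope
Title: Pareto Task Inference for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits minimal enclosing polytopes (principal convex hull /
    archetypal analysis) to cells in gene-expression space, selects the
    number of archetypes from the explained-variance curve, tests polytope
    significance against column-shuffled nulls (explained variance and
    t-ratio statistics), characterizes archetypes by leave-one-out binned
    gene enrichment and gene-set enrichment with bootstrap robustness, and
    quantifies how uniformly cells fill their polytope. Includes
    modality-specific preprocessing for single-cell qPCR, mass cytometry
    and RNA-Seq matrices, and a synthetic-data generator for polytope-shaped
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    clue,
    class,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
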