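Package: gsreg
Title: Gene Set Regularity Analysis of Expression Functionomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-conservation scoring of gene sets in expression cohorts.
    Builds majority pairwise-ordering templates from a normal control cohort,
    scores every sample's gene set regularity (GSR) index against them, and
    assembles the per-sample functionome (one GSR index per gene set) and
    immunofunctionome (the Gene Ontology offspring of immune system process
    and inflammatory response). Provides the downstream staged inference:
    control-mean correction of group means, Mann-Whitney testing with
    Benjamini-Hochberg correction, per-stage significance ranking, top-k
    cross-stage intersection, progressive-deregulation filtering,
    core/auxiliary element extraction by ontology semantic similarity, and
    support vector machine classification of functionome profiles with
    repeated cross-validation. Ships a synthetic-cohort generator with
    planted, graded rank-order disruption for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    kernlab,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
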