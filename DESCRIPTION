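Package: coexmod
Title: Cross-Cohort Gene Co-Expression Modules, Reporter Features and
    Expression-Based Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-cohort gene co-expression networks from TPM
    expression matrices (Spearman correlation, Benjamini-Hochberg FDR
    screening, top-decile positive edge retention), detects modules by
    Leiden modularity optimisation, quantifies module conservation across
    cohorts (Jaccard index, hypergeometric overlap, consensus modules),
    computes module topology (degree, closeness centrality) and degree
    concordance, performs hypergeometric over-representation against gene
    set and transcription-factor target collections, scores reporter
    metabolites and reporter transcription factors by inverse-normal
    aggregation of differential-expression p-values with sampled
    background correction, and classifies genes as favourable or
    unfavourable prognostic markers by Kaplan-Meier optimal-cutpoint
    scanning with log-rank tests. A synthetic multi-cohort data generator
    with planted co-expression modules, bipartite regulatory maps and
    expression-dependent survival supports end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
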