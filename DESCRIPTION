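Package: rrtempo
Title: Temporal Transcriptome Patterns Across Meditation Practice Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for temporal transcriptome analysis of a single
    relaxation-response practice session measured in three practice groups
    (novices, short-term and long-term practitioners) at three timepoints.
    Implements moderated differential expression with random-variance t-tests
    and permutation p-values, self-organizing-map discovery of temporal
    expression patterns, a gene set enrichment engine for two-class and
    continuous-covariate phenotypes with permutation significance, rule-based
    classification of enriched sets into Progressive and Long-term temporal
    patterns, enrichment-map merging of gene sets into modules, and
    bottleneck-centrality identification of focus hubs in molecular
    interaction networks. Includes a synthetic-data generator with planted
    group-by-time structure for power and calibration studies, and readers
    and writers for the GCT, CLS, GMT and SIF formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
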