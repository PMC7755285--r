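Package: coexhub
Title: Weighted Gene Co-Expression Modules and Hub-Gene Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from bulk
    expression matrices (soft-threshold adjacency with scale-free fit
    diagnostics, topological overlap), detects co-expression modules by
    average-linkage clustering with a dynamic-hybrid tree cut, summarizes
    modules by eigengenes, screens hub genes by intramodular connectivity
    and module membership (kME) with Student t p-values, and nominates
    final candidates through local hypergeometric gene-set enrichment and
    multi-term intersection. Ships a synthetic-data generator with planted
    modules, known kME and hub genes for end-to-end validation, and a
    single-call pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Network, GeneExpression, Clustering, NetworkInference,
    Transcriptomics
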