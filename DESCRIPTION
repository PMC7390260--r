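Package: omicslink
Title: Knowledge-Driven Integration of Transcriptomic and Metabolomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates a sample-matched transcriptomic matrix (HGNC gene
    symbols) with a metabolomic matrix (ChEBI identifiers) through a
    knowledge-driven workflow: metabolites are mapped to pathways via an
    offline ChEBI-to-Reactome snapshot (with ontology-tree fallback to the
    nearest mapped child or parent), the pathway gene sets are expanded with
    high-confidence interaction-network neighbours, correlated features are
    pruned within each set, and the two reduced sets are related by canonical
    correlation analysis with full diagnostics (weights, loadings, adequacies,
    communalities, redundancies, Bartlett sequential tests, helio-plot tables)
    and by NIPALS partial least squares regression with cross-validated
    RMSEP/MSEP/R2 prediction-error curves. Includes generators for paired
    matrices with planted canonical structure and for miniature knowledge-base
    snapshots, so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
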