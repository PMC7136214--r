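Package: metrep
Title: Reporter Metabolite and Metabolic Co-Expression Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes condition-specific metabolic rewiring by
    integrating differential gene expression with a genome-scale metabolic
    model. Implements the reporter metabolite statistic (inverse-normal
    gene scores aggregated over each metabolite's enzyme neighborhood,
    corrected against a random-gene-set background) and its pathway-level
    aggregation, with directional (up/down) runs; and a signed weighted
    co-expression analysis of metabolic genes (signed similarity,
    soft-threshold adjacency, topological overlap, dendrogram module
    detection, SVD eigengenes, module-trait correlation, hypergeometric
    pathway enrichment). Includes count-matrix normalization by median of
    ratios, a paired differential-expression stage, fold-change PCA, and
    synthetic-data generators with planted truth so every stage can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
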