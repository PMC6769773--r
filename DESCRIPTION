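Package: plasmir
Title: Plasma Circulating miRNA Profiling Pipeline for Staged Ovarian Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plasma circulating microRNA profiles measured
    on a hybridization-counting (NanoString nCounter style) panel across healthy
    controls and FIGO-staged ovarian cancer cohorts. Provides three-stage count
    normalization (negative-control background subtraction, positive-control lane
    correction, housekeeping scaling), Kruskal-Wallis testing with Dunn post hoc
    comparisons and cohort fold changes, stratification of differential miRNAs
    into expression groups, qPCR 2^-deltaCt validation with a 45-cycle ceiling,
    miRNA-target bipartite network construction and centrality ranking, target-set
    intersection, hypergeometric over-representation analysis against GMT gene-set
    collections, seed-based protein-protein interaction minimum-network extraction
    with hub ranking, and a seeded synthetic-data generator that emulates every
    input so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
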