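Package: cenweaver
Title: Integrated Gene Co-Expression Network Construction with Mutual Ranks
    and Topological Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds bulk RNA-seq gene co-expression networks by integrating a
    hard-threshold Pearson correlation / mutual-rank (MR) strategy with a
    soft-threshold topological overlap (TOM) strategy. Provides 3-sigma
    low-TPM gene filtering, directional correlation ranks and their geometric
    means, scale-free soft-power selection, unsigned TOM edge extraction,
    ROC/AUC evaluation of edge sets against annotation-derived gold standards,
    AUC-driven correlation-threshold optimization, edge-set integration with
    provenance, network and transcription-factor family subnetwork statistics,
    hypergeometric term enrichment, and a seeded planted-module expression
    simulator so every stage is testable without external data.
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
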