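Package: idlda
Title: Diffusion-Based Ranking of lncRNA-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks candidate long non-coding RNA (lncRNA) to disease
    associations on a bipartite association network with a two-pass
    resource-diffusion model seeded from similarity-smoothed association
    matrices. Disease similarity combines MeSH directed-acyclic-graph
    semantic similarity with a Gaussian interaction-profile kernel; lncRNA
    similarity combines best-match functional similarity over associated
    disease sets with the corresponding kernel. Includes global
    leave-one-out and local row/column cross-validation with tie-corrected
    AUROC, alpha/beta grid search, fold-enrichment analysis, synthetic
    network and MeSH-forest generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
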