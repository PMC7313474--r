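Package: switchscan
Title: Switch-Gene Mining in Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies switch genes -- anti-correlated, module-straddling
    hubs that mark transitions between biological conditions -- from
    two-condition expression matrices. Implements differential filtering with
    an adaptive fold-change threshold, signed Pearson co-expression networks,
    k-means community detection with SSE scree selection, network heat
    cartography (within-module degree z-score, clusterphobic coefficient,
    average neighbor correlation), fight-club-hub and switch-gene extraction,
    targeted node-removal robustness curves, cross-condition set comparison
    with biclustering, and database-agnostic downstream annotation
    (hypergeometric over-representation, minimum connected protein-protein
    interaction subnetworks, regulator and chemical ranking). Ships a
    synthetic-data generator with planted correlation modules and planted
    switch genes so every pipeline stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
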