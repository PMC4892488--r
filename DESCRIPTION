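Package: coexdiff
Title: Differential Weighted Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds signed weighted gene co-expression networks for two
    sample conditions, detects modules by average-linkage clustering of the
    topological overlap dissimilarity with a hybrid dynamic tree cut,
    scores cross-condition module preservation with permutation Z
    statistics (Zsummary), selects weakly preserved disease modules, ranks
    candidate genes by differential betweenness centrality, and tests
    module gene sets for pathway over-representation. Includes a
    two-condition synthetic expression generator with planted modules so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
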