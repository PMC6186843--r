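Package: mstmkl
Title: Maximum Spanning Tree Brain Networks with Multikernel SVM Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds unbiased maximum-weight spanning-tree functional brain
    networks from region-of-interest time series, extracts complementary
    local (betweenness centrality) and topological (discriminative frequent
    subgraph) properties, and classifies two-group cohorts with a weighted
    multikernel support vector machine under repeated stratified
    cross-validation. Includes a frequent-subgraph miner for uniquely
    labeled graphs, a Weisfeiler-Lehman subtree graph kernel, and a
    synthetic cohort generator with planted hub and motif effects for
    validation without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    kernlab,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
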