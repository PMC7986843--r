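Package: netstab
Title: Bootstrap Stability of Module Detection in Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the stability of modules (communities) detected in
    correlation networks using nonparametric bootstrap resampling of the
    observations. Stability is measured through Jaccard co-membership of
    nodes at three levels: individual nodes, detected modules, and the
    whole graph. A gap-style statistic compares the observed unconditional
    stability against the expected stability of degree-preserving random
    graphs with no module structure, and selects the absolute-correlation
    threshold that maximizes the difference. Includes a block-diagonal
    correlation simulator, a Gaussian graphical sampler, a Bonferroni
    p-value baseline for graph construction, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    mclust,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
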