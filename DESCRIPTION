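Package: modnet
Title: Consensus Module-Network Inference of Transcription-Factor Regulation from RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A module-network pipeline for inferring signed transcription-factor
    to gene-module regulatory interactions from bulk RNA-seq count matrices.
    Counts are normalized by the median-of-ratios estimator and summarized as
    FPKM; differentially expressed genes are called under a fold-change and
    p-value filter and grouped into co-expression modules by K-means with the
    number of clusters selected by a spherical-Gaussian BIC sweep; every
    regulator-module pair is then scored by an ensemble of four network
    inference algorithms (ARACNE, CLR, LARS stability selection, and shrinkage
    partial correlation), votes are combined by k-of-n consensus, and edges are
    classified as activators or suppressors from a signed rank-based consensus
    score. A negative-binomial simulator with a planted bipartite regulator
    network provides ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
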