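Package: eegtopo
Title: Higher-Order Topological Features and Graph Convolutional
    Classification of EEG Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies stroke severity (mild versus moderate, by NIHSS)
    from multichannel EEG. Band-filtered signals are turned into functional
    connectivity graphs (Pearson correlation, phase-locking value), whose
    distance matrices feed Vietoris-Rips persistent homology. Persistence
    diagrams are vectorized as persistence landscapes, Betti curves and
    persistent entropy; the resulting higher-order descriptors are fused
    with conventional time-, frequency- and network-domain node features
    and classified with a lightweight dense graph convolutional network.
    Includes a synthetic cohort generator with planted phase-coupling
    topology, SMOTE class rebalancing, subject-wise cross-validation, and
    cycle-ratio analysis of key brain regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
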