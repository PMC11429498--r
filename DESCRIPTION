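Package: stgcnad
Title: Skeleton-Based Behavior Classification and Abnormal-Behavior Detection
    with an Enhanced Spatio-Temporal Graph Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing animal pose-keypoint trajectories.
    Reads DeepLabCut-style keypoint tables, assembles fixed-length skeleton
    clips, and encodes them with a spatio-temporal graph convolutional
    network extended with a Gaussian-noise adjacency perturbation,
    squeeze-and-excitation channel attention, and a multi-branch dilated
    temporal convolution. The encoder and softmax classifier are trained
    with stochastic gradient descent on normal behavior only; abnormal
    clips are then flagged semi-supervised by projecting clip embeddings
    with principal component analysis and density-clustering them with
    DBSCAN, where points outside every cluster are reported as anomalies.
    Includes a kinematic simulator of top-view mouse behavior (movement,
    head turning, standing, turning) with parameterised anomaly families
    so the full pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
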