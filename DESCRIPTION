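Package: braintopo
Title: Distance-Based Topological Indices for Pixel-Graph Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts grayscale images into pixel graphs through a brightness
    distance matrix with min-max normalization and similarity thresholding,
    computes six distance-based topological indices (Szeged, Graovac-Ghorbani,
    Padmakar-Ivan, Mostar, normalized Graovac-Ghorbani, Wiener) from per-edge
    vertex partitions, normalizes them against matched Watts-Strogatz
    small-world ensembles (including a closed-form neighbourhood count for the
    unrewired ring lattice, audited against a breadth-first-search oracle), and
    classifies multi-stage labels from the resulting six-feature vectors with
    SMOTE balancing, stratified cross-validation, and four classifier families.
    Includes a synthetic image generator emulating class-conditional texture
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    yaml,
    jsonlite,
    pROC,
    rpart,
    nnet,
    e1071,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
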