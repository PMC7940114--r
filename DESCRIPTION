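Package: embedfcn
Title: Embedded Functional Connectivity Networks from Parcellated fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs functional connectivity networks (FCN) from parcellated
    resting-state fMRI time series using a lag-maximized cross-correlation
    pseudo-distance, optionally embeds the distance matrices on a low-dimensional
    manifold with ISOMAP (k-nearest-neighbour graph, geodesic distances, classical
    multidimensional scaling), thresholds them proportionally into weighted graphs,
    and computes five local graph-theoretic node measures (strength, local
    efficiency, local clustering, betweenness centrality, participation
    coefficient).  Subjects are classified with a linear support vector machine
    inside a double leave-one-out cross-validation scheme whose inner loop performs
    feature selection by LASSO (with the one-standard-deviation rule) or by random
    forest mean-decrease-Gini ranking with subset search.  A seeded synthetic
    cohort generator with modular correlation structure and planted group
    differences makes the whole pipeline testable without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    e1071,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    kernlab,
    vegan,
    optparse
Config/testthat/edition: 3
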