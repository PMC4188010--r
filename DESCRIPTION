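Package: dropRank
Title: Texton-Based Scoring and Ranking of Protein Crystallization Droplet
    Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores and ranks robotically captured protein crystallization
    droplet images by the posterior probability that they contain crystals or
    crystalline behaviour. Droplets are described by frequency histograms of
    textons (prototype vectors of rotation-invariant filter-bank responses);
    the texton dictionary is built by two-stage clustering (per-image
    variational Bayes Gaussian mixtures followed by DP-means). The pipeline
    includes empty-plate background registration, fault detection with a
    random forest on gradient and droplet-shape features, droplet boundary
    tracing by a circular shortest path in polar coordinates, shadow gamma
    correction, radial boundary extension, and plate-level ranking and score
    profiles. A seeded synthetic plate-image generator with ground-truth
    masks supports end-to-end testing without institutional image archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    randomForest,
    png,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    jsonlite
biocViews: Classification, Clustering, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dictionary.R'
    'dpmeans.R'
    'faults.R'
    'filterBank.R'
    'pipeline.R'
    'preprocess.R'
    'ranking.R'
    'segmentation.R'
    'synthetic.R'
    'textons.R'
    'utils.R'
    'vbgmm.R'
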