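Package: enmtransfer
Title: Evaluating Temporal Transferability of Ecological Niche Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A paired-model protocol for assessing how well correlative
    ecological niche models (ENMs, also called species distribution models)
    transfer through time. Models trained on historical occurrence and
    climate data are projected to modern climate and compared against
    models trained directly on modern data, in both environmental space
    (Schoener's D) and geographic space (stable cells, range-size
    variation, and the Euclidean distance to the theoretical-best
    performance point). The package ships a seeded virtual-species world
    generator (drifting monthly climates, Gaussian niches, weighted
    occurrence sampling), bioclimatic variable derivation with
    Thornthwaite potential evapotranspiration, the occurrence-cleaning
    cascade (cell thinning, Mahalanobis ellipsoid outlier screening,
    overlap-maximizing dataset balancing), a pluggable algorithm layer
    (BIOCLIM, DOMAIN, kernel density estimation, logistic GLM and other
    classifier adapters, weighted ensembles), replicated subsampling
    workflows with prevalence-calibrated probabilistic binarization,
    model evaluation metrics (AUC, 10 percent omission rate, partial ROC,
    continuous Boyce index, mobility-oriented parity), and nonparametric
    comparison statistics (Kruskal-Wallis, pairwise Mann-Whitney with
    Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    rpart,
    nnet,
    randomForest,
    e1071,
    mgcv,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
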