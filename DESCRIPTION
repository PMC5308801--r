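Package: riemsway
Title: Riemannian Covariance Analysis of Postural Sway from Markerless
    Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies postural-stability conditions and seated balance
    tasks from multivariate kinematic time series: skeletal joint
    trajectories recorded by a markerless depth camera at 30 Hz and
    center-of-pressure traces from a force platform at 600 Hz.  Trials
    are summarised by spatial covariance matrices, treated as points on
    the manifold of symmetric positive-definite matrices under the
    affine-invariant metric, mapped to a tangent space anchored at the
    log-Euclidean mean, and classified with regularised multinomial
    logistic regression.  Condition prediction ensembles six per-task
    models by probability summation and is evaluated by
    leave-one-subject-out cross-validation.  Includes device agreement
    benchmarking (Pearson correlation and RMSE between trunk centroids
    and center of pressure), Riemannian distance matrices with t-SNE
    embedding, and a synthetic paired-device generator so the whole
    pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Rtsne,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
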