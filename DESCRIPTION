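Package: liverbench
Title: Benchmarking Complete-to-Partial Point Cloud Registration for Laparoscopic Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained benchmark for complete-to-partial rigid point-cloud
    registration in laparoscopic liver surgery. Synthesizes deformed, partial, noisy
    intraoperative-style liver point clouds from a procedural two-lobed liver phantom
    with full ground truth (rigid transform, point correspondences, overlap labels,
    target-registration-error landmarks); implements classical registration baselines
    (ICP, rigid coherent point drift, Gaussian-mixture L2 registration, FPFH descriptor
    matching with RANSAC, weighted Kabsch-Umeyama pose estimation) together with a
    complete-to-partial overlap head and its training losses as pure operations; and
    evaluates all methods with rotation/translation mean absolute errors and landmark
    target registration error aggregated across partiality levels.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
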