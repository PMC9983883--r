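Package: alphareg
Title: Symmetric Deformable Image Registration with Fuzzy Alpha-Cut Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mono-modal deformable image registration for 2D images and 3D
    volumes. Images are treated as spatial fuzzy sets and matched by an
    alpha-cut point-to-set distance estimated by Monte Carlo sampling over an
    augmented max KD-tree, combined with an inverse-inconsistency penalty that
    promotes symmetric (approximately invertible) transformation pairs. The
    transformation model is a cubic B-spline free-form deformation optimized
    by stochastic gradient descent with momentum in a coarse-to-fine schedule
    with quasi-random (Kronecker) and gradient-weighted point sampling.
    Includes a synthetic vessel-phantom generator with known ground-truth
    warps and the standard evaluation metrics (Jaccard index, mean landmark
    error, target overlap, success-rate curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
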