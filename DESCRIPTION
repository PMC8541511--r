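Package: valveseg
Title: Unsupervised Mitral Valve Segmentation in Echocardiographic Videos
Version: 0.1.0
Authors@R:
    person("Valveseg", "Maintainers", email = "maintainers@valveseg.org",
           role = c("aut", "cre"))
Description: Fully automatic, unsupervised segmentation of the mitral valve in
    two-dimensional echocardiographic videos. Separates the rigidly moving
    myocardium from the fast, non-rigidly moving valve by a bias-free robust
    nonnegative matrix factorization (multiplicative updates debiased by
    Bregman iterations), segments the sparse component with a convex-relaxed
    Chan-Vese energy solved by a primal-dual hybrid gradient scheme, refines
    the binary mask by an iterative Gaussian-attenuated centroid and
    spatiotemporal connected-component selection, and optionally localizes the
    valve with a window scan over an exclusion-regularized factorization.
    Includes a synthetic phantom generator with voxel-level ground truth so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
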