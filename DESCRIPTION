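Package: wdbcm
Title: Weight-Dependent BCM Plasticity with Feed-Forward Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the Bienenstock-Cooper-Munro (BCM)
    synaptic plasticity rule with a sliding modification threshold, extended
    with weight-dependent (soft-bound) depression and fixed feed-forward
    inhibition. Provides stimulus-ensemble generators (mirrored two-pattern
    pairs, circulant triangular and von Mises profiles, difference-of-Gaussians
    filtered image patches with a synthetic 1/f image source), a compiled
    Euler simulator of the learning dynamics with optional post-synaptic
    noise, analytic and numerical fixed-point machinery (null-clines,
    piecewise-Jacobian stability, critical inhibition levels, noisy fixed
    points), selectivity and excitation/inhibition imbalance metrics,
    selectivity phase diagrams, and reproducible command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    EBImage,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
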