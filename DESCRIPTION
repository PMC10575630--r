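Package: mesoframe
Title: Y-Maze Behavior, Miniscope Calcium Ensembles, and Dopaminergic
    Histology Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a classic miniscope study
    pipeline: spontaneous-alternation scoring in the three-arm Y-maze,
    PCA/ICA extraction of neuronal components from one-photon calcium
    movies with skewness- and vessel-based component selection,
    derivative-based calcium event detection, position-binned ensemble
    and alternation-selectivity analysis, Laplacian/Hessian quantification
    of dopaminergic boutons and axons in confocal images, and the
    accompanying statistical battery. Every stage is exercised end-to-end
    on synthetic data with known ground truth: a biased maze agent,
    position-tuned GCaMP6s-like transients rendered into movies, and
    histology phantoms of curvilinear axons with planted boutons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tiff,
    e1071,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
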