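Package: boutonkit
Title: Detection and Probabilistic Tracking of Axonal Boutons in Two-Photon
    Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated analysis of axonal boutons in 3D two-photon
    laser scanning microscopy (2PLSM) stacks. Refines manually traced axon
    centerlines against the image, generates multi-scale
    Laplacian-of-Gaussian and Gaussian intensity profiles along the trace,
    decomposes profiles into constrained foreground/background Gaussian
    peaks to detect putative boutons and measure normalized bouton weights,
    and scores structural plasticity (addition, elimination, potentiation,
    depression) probabilistically under an explicit measurement-noise
    model. Includes a synthetic-data generator that renders ground-truth
    axons with boutons, anisotropic point-spread function and noise, so
    the full pipeline can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
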