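Package: pseudodect
Title: Pseudo Dual-Energy CT Simulation, Material Decomposition, and Iodine Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and analysis workflow for generating pseudo
    dual-energy CT (DECT) from single 120-kVp CT scans of digital electron-density
    phantoms. Provides polychromatic x-ray spectrum models and XCOM-derived
    attenuation tables; digital calibration and evaluation phantoms with rod
    inserts and iodine syringes; a Siddon ray-tracing forward projector and
    filtered-backprojection reconstructor; projection-domain two-material
    (aluminum/acrylic) decomposition parameterized on a simulated step wedge;
    virtual monochromatic CT synthesis and iodine quantification via an
    origin-constrained conversion factor; a small patch-based convolutional
    network trained with stochastic gradient descent that maps 120-kVp images to
    pseudo 80- and 140-kVp images; and image-quality metrics (RMSE, PSNR, CNR,
    coefficient of variation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
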