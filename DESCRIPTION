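Package: ipdtplan
Title: Interstitial Photodynamic Therapy Planning Under Light-Delivery Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Treatment planning and robustness analysis for interstitial
    photodynamic therapy (iPDT). Generates synthetic layered brain-like
    tissue phantoms with labelled tumour and organ-at-risk regions, computes
    light fluence fields for point and cylindrical (line) diffusers with a
    diffusion-approximation kernel or a voxel Monte Carlo photon transport
    engine, optimizes per-source powers with a linear-program dose objective
    (including uncertainty-aware minimum-power and max-plus-min variants),
    optimizes source placement by simulated annealing, and quantifies the
    effect of source-power and source-position uncertainty on dose-volume
    (v100) outcomes via worst-case bounds, discretized angular-deflection
    libraries, truncated-Gaussian sampling, and power re-optimization on
    realized source positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
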