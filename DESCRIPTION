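Package: wingbone
Title: Bone Laminarity, Cross-Sectional Geometry, and Phylogenetic Scaling of Wing Bones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the histological and mechanical organization of
    wing bones in flying vertebrates. Measures and classifies primary vascular
    canals in transverse cortical sections (octant extraction, periosteal
    straightening with deformation validation, moment-based ellipse fitting, the
    four-way longitudinal/circumferential/radial/oblique orientation criteria)
    and estimates the laminarity index with a small-sample Wilson proportion
    interval. Computes cross-sectional geometry of cortical profiles (cortical
    and total area, principal second moments of area, polar moment, polar
    section modulus, shape ratio). Derives maximum growth rate, mass at
    inflection and relative growth rate from logistic, Gompertz and von
    Bertalanffy growth curves, and mass-specific field metabolic rate. Fits
    allometric log-log scaling regressions by ordinary and phylogenetic
    generalized least squares under Brownian-motion and Ornstein-Uhlenbeck
    covariance with REML, gated by a permutation test of Blomberg's K and a
    residual runs test, with AICc model selection. Includes synthetic-data
    generators (canal fields, cortical masks with closed-form geometry, growth
    series, pure-birth trees with phylogenetically correlated traits) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    EBImage,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    nlme,
    picante,
    tiff,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
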