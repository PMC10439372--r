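Package: cuffmc
Title: Probabilistic Rotator Cuff Force Prediction During Bimanual Arm Suspension
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative probabilistic glenohumeral modelling of human and
    chimpanzee rotator cuff function during the support phase of horizontal
    bimanual arm suspension. Provides species parameter sets (anthropometry,
    muscle physiological cross-sectional areas, attachment-site distributions,
    directional glenoid stability ratios), synthetic posture and bone-geometry
    fixtures, string-muscle path geometry with spherical and cylindrical
    wrapping, static inverse dynamics of the support phase, stability-constrained
    muscle-force optimization with a stress-based objective, Monte Carlo
    uncertainty propagation over fourteen morphological inputs with cumulative
    distribution functions at eleven probability levels, mean-perturbation
    sensitivity factors, and between-species distribution overlap reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
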