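Package: cvrflow
Title: Cerebrovascular Reactivity Quantification from 4D Flow MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cerebrovascular reactivity (CVR) to hypercapnia from
    velocity-encoded (4D flow) phase-contrast MRI. Provides a synthetic
    Poiseuille flow-phantom generator with analytic ground truth, velocity
    aliasing (phase-wrap) correction, eddy-current/background phase-offset
    correction from static tissue, PC-MRA angiogram computation, vessel lumen
    segmentation with centerline extraction and labeling, per-vessel blood
    flow and cross-sectional area measurement on centerline-perpendicular
    planes, cerebrovascular conductance (CVC = flow/MAP x 100) and CVR (slope
    of CVC versus end-tidal CO2), and the associated group statistics
    (one-way, two-way and mixed ANOVA, Holm-Sidak step-down, t tests,
    Brown-Forsythe).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    car,
    EBImage,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Preprocessing
RoxygenNote: 7.3.3
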