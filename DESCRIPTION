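Package: plaqueFatigue
Title: Thin-Slice Vessel Mechanics, Plaque Fatigue Metrics and Stenosis
    Progression Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying coronary plaque fatigue and stenosis
    progression from cross-sectional vessel geometry. Implements a
    generalized-plane-strain hyperelastic finite-element model of a thin
    vessel slice with modified Mooney-Rivlin (isotropic and
    fibre-reinforced anisotropic) materials, circumferential/axial
    shrinkage pre-processing to recover a stress-free reference from
    pressurized imaged contours, stress/strain amplitude (fatigue) and
    morphology feature extraction over the cardiac pressure cycle,
    dependence-adjusted correlation via patient-level random-intercept
    mixed models, and random-forest classification of lumen narrowing
    with out-of-bag tuning and Gini-importance backward elimination. A
    synthetic cohort generator provides IVUS-like baseline/follow-up
    slice pairs for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    lme4,
    randomForest,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
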