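Package: springsim
Title: Finite-Element Prediction of Spring-Assisted Cranioplasty Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and population-level material calibration of
    spring-assisted cranioplasty (SAC) for sagittal craniosynostosis.
    Provides parametric generation of scaphocephalic calvarium tetrahedral
    meshes with patent sutures, osteotomies and spring grooves; a logarithmic
    calvarial growth model for age rescaling; a quasi-static small-strain
    linear-tetrahedral finite-element solver with Prony-series viscoelastic
    relaxation and elastic spring-distractor coupling; central composite
    design-of-experiments sampling, quadratic response-surface fitting, local
    sensitivity analysis and box-constrained material optimization; and shape
    outcome metrics (ICP registration, surface-distance RMSE, cranial index).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
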