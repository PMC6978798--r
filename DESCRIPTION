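Package: axoncable
Title: Double-Cable Modelling of Myelinated Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biophysical modelling of myelinated axons with an
    electrically distinct periaxonal space (the double-cable circuit).
    Includes a labelled-morphology container with SWC/YAML import, the
    closed-form algebra linking passive cable parameters to axo-myelin
    ultrastructure (myelin lamellae, sheath thickness, periaxonal width),
    an implicit two-layer compartmental solver with pipette models, current
    injection and action-potential voltage clamp, Hodgkin-Huxley-style
    active extensions with conduction-velocity analytics, an evolutionary
    parameter-fitting pipeline for passive voltage transients with
    noise-constrained direction-set refinement and circuit comparison,
    saltation and onset-latency analysis, voltage-sensitive-dye calibration,
    and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
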