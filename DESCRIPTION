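Package: hpaclock
Title: Light-Entrained Limit-Cycle Modelling of HPA Axis Glucocorticoid
    Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-mechanistic modelling of the circadian
    hypothalamic-pituitary-adrenal (HPA) axis as a light-entrained
    Goodwin-type limit-cycle oscillator with glucocorticoid-receptor
    pharmacodynamics.  Provides cosinor rhythmometry and calibration
    acceptance testing, sampling of the regulatory parameter subspace
    (hypothalamic and pituitary feedback, adrenal sensitivity) under
    nominal and chronically elevated central drive, acute stress response
    scoring with symbolic partitioning, shift-work and jet-lag
    photoperiod protocols, Arnold tongue entrainment analysis, and
    Floquet stability of the entrained orbit, together with a synthetic
    corticosterone data generator so the full analysis runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
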