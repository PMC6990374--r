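Package: infarctsim
Title: Monodomain Simulation of Conduction Block and Re-Entry in Idealized
    Infarct Border Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-difference monodomain simulation of two-dimensional
    idealized infarct tissue with a ten Tusscher-Panfilov (2006) endocardial
    membrane model. Provides border-zone electrophysiological remodeling
    (reduced sodium current, prolonged action potential duration), synthetic
    patchy fibrosis with exact density control, S1-S2 premature-stimulus
    vulnerability protocols, activation/repolarization field maps, the
    re-entry vulnerability index (RVI), automated conduction-block and
    re-entry classification, and parameter sweeps producing block/re-entry
    probability tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
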