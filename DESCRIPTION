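Package: c4balance
Title: Mass- and Charge-Balanced Constraint-Based Modelling of C4 Plant Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and interrogating mass- and charge-balanced
    genome-scale metabolic models of C4 plants. Provides a tabular and SBML
    (Level 3 + FBC) model reader/writer with compartment- and role-suffix
    conventions, a curation battery (per-reaction elemental and charge
    balance, energy-leak and futile-cycle tests, blocked-reaction detection
    by flux variability analysis), multi-tissue mesophyll/bundle-sheath/stem
    model assembly with C4 shuttle wiring, a lexicographic photon-minimising
    flux balance analysis engine built on a bounded-variable simplex solver,
    declarative scenario presets for lignocellulose production and nitrogen
    source experiments under internal proton balance, and a synthetic C4
    core-model generator with analytically known ammonium:nitrate uptake
    behaviour for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
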