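Package: canardEAD
Title: Canard Analysis of Early Afterdepolarizations in a Reduced
    Luo-Rudy Action Potential Model
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a reduced four-variable Luo-Rudy I ventricular action
    potential model and analyses early afterdepolarizations (EADs) produced
    by manipulations of the L-type calcium current window region. Provides
    stimulated-response simulation with EAD counting and outcome
    classification, one- and two-parameter sweeps with bisection-refined
    region boundaries, fast-slow decomposition (critical manifold, fold
    curve, folded node singularities, singular strong canard), and
    computation of attracting and repelling slow manifolds, maximal canards,
    rotational sector assignment, and the signed distance between the pulsed
    orbit and the primary maximal canard.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
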