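Package: mstps
Title: Multiple-State Transition Path Sampling and Switching Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-state transition path sampling (MSTPS) with one-way
    shooting in a flexible-length, all-to-all path ensemble, exercised on a
    two-dimensional multi-well diffusive toy system. Includes detection of
    switches between sampled transitions, a kinetics solver for transition
    populations and switching rates from switch counts and residence times,
    Monte-Carlo-weighted path density histograms, convergence diagnostics,
    and plain-text archive and report formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
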