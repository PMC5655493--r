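Package: gwtraj
Title: Sparse Functional Principal Component Analysis of Gestational
    Weight Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs individual gestational weight trajectories from
    sparse, irregularly timed weight records using functional principal
    component analysis with conditional-expectation scores (PACE): local
    linear kernel smoothing of the mean function and covariance surface,
    eigenanalysis of the discretized covariance operator, fraction-of-
    variance-explained component selection, and pointwise and simultaneous
    confidence bands for reconstructed curves.  Includes a logistic
    nonlinear mixed-effects comparator model, gestational weight-change
    outcomes (absolute and log-relative, direct and trajectory-based), a
    regression stage relating weight change to prepregnancy body mass
    index, diet and physical activity, and a synthetic cohort generator
    that emulates a trimester-based antenatal visit design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    nlme,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
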