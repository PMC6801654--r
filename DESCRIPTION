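Package: weanres
Title: Quantifying Piglet Resilience to Weaning from Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models post-weaning live-weight trajectories of piglets with a
    piecewise Gompertz-Makeham growth law in which an environmental
    perturbation term depresses the specific growth rate until an
    animal-specific recovery switch. Provides per-animal nonlinear
    least-squares calibration (Nelder-Mead), goodness-of-fit statistics
    (r-squared, Lin's concordance correlation coefficient), AIC model
    selection against the classic Gompertz model, an area-between-curves
    (ABC) resilience index computed against an unperturbed reference curve,
    correlation screening of model parameters against faecal scores and
    haematological traits, and a synthetic cohort generator that emulates
    the measurement design of intensive pig production studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
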