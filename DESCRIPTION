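Package: agencymix
Title: Face-Motion Mixing Experiments and the Exploration-Exploitation
    Model of the Sense of Agency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing face-motion mixing
    experiments on the sense of agency. Generates synthetic two-actor
    facial-landmark experiments (2x2 within-participant design: self vs
    other face, full vs partial control), mixes motion displacement
    fields at a configurable control ratio with display latency,
    decomposes landmark trajectories into rigid head motion and
    region-wise facial-muscle motion, computes moving-distance and
    peak-switching motion-diversity metrics and motion-error control
    measures, implements a two-mode (exploitation vs exploration)
    logistic model of agency ratings with simulation and curve fitting,
    and runs the study-style statistical battery: 2x2 repeated-measures
    ANOVA with partial eta squared, Bonferroni-corrected paired
    comparisons, Cohen's d_z, d-prime, and noncentral-t power and
    sample-size analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
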