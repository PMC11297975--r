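Package: pentrial
Title: Bayesian Analysis of Unreplicated Pen Feeding Trials in Atlantic Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-factor (fish size by dietary rapeseed-oil
    level) pen feeding trials in Atlantic salmon. Implements exact Gaussian
    marginal likelihoods for five nested linear-model hypotheses with flat
    intercept and weakly informative coefficient priors, posterior model
    probabilities, Bayes factors with Kass-Raftery evidence categories,
    credible-interval regression lines, and Kolmogorov-Smirnov residual
    diagnostics. Also provides proportional-odds ordinal regression for
    histology score distributions, inert-marker apparent digestibility and
    growth/somatic calculators, mapping of steatosis-score shifts onto
    indicative choline-requirement shifts through a user-supplied
    dose-response curve, and seeded synthetic-data generators so every stage
    of the pipeline can be tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
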