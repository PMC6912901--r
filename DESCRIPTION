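Package: sdmbias
Title: Virtual-Species Simulation and Sampling-Bias Correction for
    Presence-Only Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate sex-structured presence-only occurrence data
    under spatially biased and unbiased survey designs, fit presence-only
    species distribution models in the weighted-logistic (Maxent-equivalent)
    formulation with two spatial sampling-bias corrections (targeted
    background points and a distance-to-trajectories covariate), and estimate
    habitat coefficients, sign densities, and subgroup (sex) ratios. Includes
    a synthetic landscape generator (spatially autocorrelated covariate
    rasters and habitat-biased observer trajectories), distance-decay
    detection models with binomial thinning, and a replicated experiment
    driver that quantifies estimation bias and the effectiveness of the
    corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
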