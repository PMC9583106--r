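Package: beetlecue
Title: Vector-Sum Cue Integration Models for Insect Compass Orientation
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Circular-statistics tools for analysing directional cue-conflict
    experiments in insect compass orientation. Models the noise of a celestial
    (ersatz sun) cue and a wind cue as von Mises distributions whose
    concentrations are set by cue reliability (sun elevation, wind speed),
    implements five integration strategies (winner-take-all, weighted
    arithmetic mean, optimal weighted vector sum, sigmoid-adjusted non-optimal
    vector sum, and a biased variant with per-individual Gaussian weight
    bias), simulates cue-conflict populations, and compares models against
    observed changes in heading with binned-likelihood, AIC and BIC scores.
    Includes the empirical exit-angle pipeline (normalisation, Rayleigh
    exclusion screens, menotaxis classification, precision summaries) and a
    synthetic-data generator with known-truth manifests for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
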