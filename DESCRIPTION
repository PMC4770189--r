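Package: orchardgrowth
Title: Thermal-Time Growth Analysis of Apple Tree Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classical growth analysis of apple tree organs on a thermal-time
    axis. Accumulates growing degree days (GDD) from hourly air temperature
    after full bloom, estimates organ dry mass through allometric models
    (spheroid fruit volume, a trunk circumference power law, and AIC-selected
    linear dry-weight models for shoots and fruits), computes interval
    relative elongation and growth rates (RER/RGR), extracts maximum
    potential growth (spur filtering, proleptic/epicormic classification,
    top-k shoot selection, max-trunk tree, thinned-fruit mean), and compares
    treatments per measurement date with one-sided Mann-Whitney and Welch
    t-tests under Bonferroni correction. A synthetic-orchard generator with
    known ground truth (logistic shoot elongation, expolinear fruit growth
    with fruit-set jitter, exponential trunk biomass) supports recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
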