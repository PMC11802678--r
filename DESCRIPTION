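Package: oxstab
Title: Ozone Flux-Based Critical Levels from Oxidative Stability of Conifer Needles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ozone flux-based critical levels against oxidative
    stability for conifers. Converts electrolyte-leakage conductivity assays
    into injury indices, extrapolates the zero-ozone baseline by log-linear
    exponential regression, computes the oxidative-stability statistic,
    inverts polynomial dose-response curves at the 5 percent injury threshold,
    detects the growing season and converts cumulative ozone exposure metrics
    (sumO3, avgO3, AOT40), runs a multiplicative (Jarvis-type) stomatal
    conductance model with hourly stomatal ozone flux and phytotoxic ozone
    dose (POD) accumulation, projects flat-profile critical levels and
    tolerance-utilisation ratios, and compares GC-MS terpenoid composition
    profiles across ozonation categories with one-way ANOVA. Includes seeded
    synthetic-data generators so the full pipeline runs without external data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
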