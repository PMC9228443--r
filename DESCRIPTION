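Package: fructanUF
Title: Response-Surface Optimization and Limiting-Flux Modeling of Agave
    Fructan Ultrafiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the fractionation of agave fructans into
    fructooligosaccharides (FOS) and long-chain fructans (Fc) by tight
    ultrafiltration.  Implements the separation-factor and solute-flux
    metrics, three-factor Box-Behnken designs with coded/actual unit
    transforms, linear and quadratic response-surface fits with Type-III
    ANOVA (lack-of-fit and pure-error partitioning from centre-point
    replicates), desirability-function multi-response optimization, a
    batch-mode ultrafiltration simulator driven by a concentration-
    polarization limiting-flux law, calibration of the mass-transfer
    coefficient and limit concentration from flux-versus-concentration
    data, rejection-versus-composition correlations, and seeded synthetic
    data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
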