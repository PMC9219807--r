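Package: allopred
Title: Single-Species Allometric Projection of Antibody-Drug Conjugate
    Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Avery", "Collins", email = "avery.collins@example.org",
           role = c("aut", "cre"))
Description: Predicts human concentration-time profiles and pharmacokinetic
    parameters (AUC, clearance, half-life) of antibody-drug conjugates and
    other biologics from a single animal species (rat or monkey) using
    fixed-exponent allometric scaling. Implements eight concentration-time
    projection methods built on dose-ratio and body-weight-ratio powers
    (including piecewise exponent switching at day 14), fixed-exponent
    scaling of clearance (0.85) and half-life (0.15), a noncompartmental
    analysis engine (trapezoidal AUC, terminal slope, half-life, clearance),
    a fold-error evaluation layer (predicted/observed ratios, fold-error
    range counts, average fold error), and a two-compartment synthetic
    pharmacokinetic simulator with configurable allometric exponents,
    lognormal residual noise and LLOQ censoring for end-to-end validation.
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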