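Package: mixaero
Title: Constrained Mixture Design, Scheffe Polynomial Modelling and
    Aerosol Performance Metrics for Nanoemulsion Formulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for optimizing drug-loaded nanoemulsion formulations by
    mixture design of experiments. Defines bounded mixture design spaces
    with pseudo-component coding, constructs candidate points (extreme
    vertices, edge midpoints, face centroids) and selects D-optimal
    designs by point exchange; fits Scheffe canonical polynomials
    (linear, quadratic, special cubic) by no-intercept least squares with
    mixture-model ANOVA, lack-of-fit and adequate-precision diagnostics;
    performs multi-response desirability optimization and residual
    standard error validation; and computes aerosolization metrics
    (span, emitted dose, percent dispersed and inhaled, MMAD, GSD, fine
    particle fraction) from laser-diffraction percentiles and cascade
    impactor stage depositions. Includes the reference docetaxel- and
    curcumin-loaded nanoemulsion study dataset and seeded synthetic-data
    generators for both the regression and impactor stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
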