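Package: irfa
Title: Immunoreactive Fraction Assay Modelling and Estimator Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the immunoreactive-fraction assay (IRFA) used in quality
    control of radiolabeled antibodies. Implements the exact antigen-depletion
    binding isotherm, the rectangular-hyperbola and Lindmo double-inverse
    estimators of the immunoreactive fraction and dissociation constant, a
    four-component stochastic error-propagation model, a pseudo-first-order
    nonequilibrium kinetic model with plate-saturation and desorption
    scenarios, and a Monte-Carlo engine comparing the accuracy, precision and
    robustness of the two estimators. Plate gamma-count reduction and assay
    design helpers are included for analysing real microplate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
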