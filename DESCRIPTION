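Package: alcocea
Title: Economic Evaluation of Alcohol Harm-Reduction Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized economic evaluation of alcohol harm-reduction
    interventions: ingredients-based (bottom-up) costing with annualization of
    capital items, cross-jurisdiction cost and benefit transfer via wage,
    purchasing-power-parity and pre-tax drink-price ratios, monetization of
    health gains and their conversion to quality-adjusted life years (QALYs)
    through a value of a statistical life year (VSLY), and computation of
    benefit-cost ratios (BCR) and incremental cost-effectiveness ratios (ICER)
    with willingness-to-pay threshold classification and league tables. Ships
    the published Western Australian intervention tables as fixtures, a VSLY
    calibration routine that inverts printed ICERs, a consistency checker for
    printed rounding, and a seeded synthetic portfolio generator with
    closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
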