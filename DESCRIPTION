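Package: octlens
Title: Optimal Cooking Time Estimation for Mixed-Maturity Lentil Seed Lots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the optimal cooking time (OCT) of lentil
    seed lots composed of mixed maturity categories from texture-analyzer
    penetration data. Implements sensory-instrumental threshold calibration
    (inverting an organoleptic doneness score onto instrument units with
    confidence bands), exponential-decay modelling of seed softening with
    threshold bracketing and curve inversion, a cooked-seed-fraction
    statistic that counts overcooked seeds as cooked and scales measured
    readings to whole-subsample counts, three-parameter sigmoid modelling of
    the cooked fraction with OCT prediction at a target percentage,
    factorial analysis of variance with eta-squared effect sizes and
    Duncan's new multiple range test, a validation stage, and a synthetic
    cooking-experiment generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
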