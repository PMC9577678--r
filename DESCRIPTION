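Package: mtmsim
Title: Policy Simulation of National Insurance Coverage of Medically
    Tailored Meals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probabilistic cohort policy-simulation model of national
    insurance coverage of medically tailored meals (MTMs) for US adults with
    diet-sensitive conditions and limitations in instrumental activities of
    daily living. Generates synthetic person-level populations calibrated to
    published survey moments (payer strata, right-skewed expenditures,
    overdispersed hospitalization counts, diagnosis prevalences), pools
    study-level effect sizes by DerSimonian-Laird random-effects
    meta-analysis, models screening and meal-contract program costs, and
    propagates joint uncertainty through 1000-replicate Monte Carlo
    simulations to estimate averted hospitalizations, averted health care
    expenditures, program costs, and net policy cost savings by payer.
    Includes 10-year open-cohort projections with log-linear growth and
    discounting, coverage and restricted-eligibility scenarios, effect-size
    percentile sweeps, and break-even threshold solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
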