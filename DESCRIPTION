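Package: calorflex
Title: Basal Metabolic Rate, Substrate Oxidation and Insulin-Sensitivity
    Associations from Indirect Calorimetry
Version: 0.1.0
Authors@R:
    person("FIT", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline from breath-by-breath gas-exchange recordings to
    basal metabolic rate (abbreviated Weir equation), basal fat and
    carbohydrate oxidation (Frayn stoichiometry), insulin-sensitivity
    indices (HOMA-IR, QUICKI), metabolic-phenotype classification, and
    covariate-adjusted association analyses with standardized coefficients.
    Includes steady-state window detection via coefficient-of-variation
    criteria on epoch-averaged series, and a seeded synthetic-data
    generator (cohort tables and breath-level traces with planted effects)
    so that every stage is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
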