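Package: coivis
Title: Prevalence-Based Cost-of-Illness Modelling for Diabetes-Related
    Visual Impairment and Blindness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, prevalence-based cost-of-illness model for
    diabetes-related visual impairment and blindness, parameterized for the
    Kingdom of Saudi Arabia. Builds a population cascade over diabetic
    retinopathy and maculopathy severity grades with an overlap correction
    factor, costs each grade's treatment protocol, expected adverse events,
    and supportive care, values productivity losses of patients and
    caregivers by the human capital method together with government
    pensions, converts totals to international dollars at purchasing power
    parity, and ranks parameter influence with one-way deterministic
    sensitivity analysis (tornado diagram). Model inputs are declarative
    YAML/JSON configurations; a seeded synthetic-scenario generator with an
    independent costing oracle supports verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
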