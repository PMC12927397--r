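Package: telemediate
Title: Interventional-Effects Mediation Analysis of Telework and Mental Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-mediator causal mediation analysis with interventional
    (in)direct effects for survey data on telework and mental health.
    Decomposes the effect of telework frequency (monthly, weekly, daily versus
    none) on anxiety, depression, burnout and work engagement into direct,
    per-mediator indirect, joint indirect and total effects via the product of
    coefficients under linear (probability) models, with nonparametric
    bootstrap standard errors, percentile confidence intervals and
    Bonferroni-Holm multiplicity adjustment per outcome. Includes survey
    coding, psychometric scale scoring (GAD-7, PHQ-9, BAT-12, UWES-3, SIMPH
    subscales) with standardised Cronbach's alpha, and a synthetic-data
    generator with known structural parameters for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
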