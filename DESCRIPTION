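Package: stigmamed
Title: Multilevel Moderated Mediation of Community Participation, Identity
    Disclosure, Victimization and Depression Under Structural Stigma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for 1-1-1 multilevel mediation and moderated mediation of
    survey data on sexual and gender minority mental health. Codes raw survey
    items into analysis variables (community participation, identity
    disclosure, victimization, depression), builds composite country-level
    structural-stigma indices from itemized law/policy tables and public
    attitude means, fits the three-model maximum-likelihood mixed-model
    sequence with within/between decomposition of level-1 predictors, and
    derives indirect effects, indices of moderated mediation, conditional
    indirect effects and Monte-Carlo confidence intervals. Includes a
    synthetic multi-country data generator with known true parameters for
    recovery and coverage testing, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
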