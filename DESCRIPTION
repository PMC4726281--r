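Package: pupsurv
Title: Early-Life Survival Analysis of Free-Ranging Dog Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Demographic and survival analysis of birth cohorts of
    free-ranging dog pups tracked from birth to a 7-month (210-day)
    horizon. Provides a cohort data model with a mortality-cause
    taxonomy (natural death, taken by humans, murdered by humans, road
    accident, no information), Kaplan-Meier estimation with Greenwood
    variance and Brookmeyer-Crowley median confidence limits, the
    two-sample log-rank test, a fixed-effects Cox proportional-hazards
    model with Efron tie correction, Aalen-Johansen cumulative-incidence
    estimation with Gray's test for group differences under competing
    risks, litter-level demographic statistics, a calibrated synthetic
    census generator, and a discrete-time cohort projection quantifying
    the survivor sex-ratio skew produced by sex-biased removal of pups
    by humans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    cmprsk,
    jsonlite,
    optparse
Config/testthat/edition: 3
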