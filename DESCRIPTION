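Package: audiotactile
Title: Analysis of Infant Audiotactile Orienting Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of lateralized orienting responses of
    infants to auditory, tactile and audiotactile stimuli presented on the
    hands. Provides constrained session-schedule generation, trial-table
    validation and filtering, dual-rater reconciliation and inter-observer
    reliability statistics (Cohen's kappa, weighted kappa, reaction-time
    agreement), random-intercept logistic and linear mixed models with
    Type III Wald chi-square tables and Bonferroni-corrected marginal-mean
    contrasts, race-model redundancy-gain analysis over reaction-time
    deciles, and a synthetic-data generator that emulates the two-group
    crossed-hands design so the whole pipeline runs without any external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
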