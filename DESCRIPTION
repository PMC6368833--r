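Package: meadowturn
Title: Species Turnover and Trait Null Models for Repeated Vegetation Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing species turnover in repeatedly surveyed
    plant communities. Computes the species exchange ratio and surveyor
    pseudo-turnover, community-mean indicator values (Landolt 1-5 scales)
    and their mixed-model temporal trends, a randomization null model
    comparing the indicator values of colonizing and disappearing species
    against random draws from the site species pool, logistic mixed models
    of per-species colonization and local survival along a nitrogen
    deposition gradient with a derived crossover deposition rate, and
    period-wise Poisson regressions of oligotrophic species richness.
    Includes a synthetic survey generator with trait-dependent community
    dynamics and imperfect detection for calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    dplyr,
    tibble,
    readr,
    glmmTMB,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
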