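Package: empyemapba
Title: Comparative Effectiveness of Empirical Anti-Pseudomonal Antibiotics
    in Empyema with Probabilistic Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative-effectiveness analysis of
    empirical anti-pseudomonal versus non-anti-pseudomonal antibiotics in
    pleural empyema: synthetic admission-record simulation, eligibility
    filtering, exposure classification, propensity-score estimation with
    average-treatment-effect inverse-probability weighting, cause-specific
    Cox proportional-hazards estimation under competing risks with robust
    (sandwich) standard errors, Aalen-Johansen cumulative incidence, summary
    tabulation with Yates-corrected chi-squared tests, and a
    nine-step probabilistic bias analysis for a binary unmeasured
    confounder. All user-facing functions take and return data frames so
    stages compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
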