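Package: careits
Title: Interrupted Time-Series Analysis of Primary-Care Contact Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying step changes and recovery slopes in weekly
    primary-care contact rates around a policy interruption, in the style of
    segmented-regression studies of pandemic-era healthcare use. Includes a
    synthetic electronic-health-record generator with a fully known
    contact-generating process (logistic trend, monthly seasonality, step and
    recovery terms, AR(1) noise), dynamic weekly cohort denominators with
    condition-specific eligibility rules, codelist-based event extraction with
    deduplication windows and composite exacerbation algorithms, quasi-binomial
    interrupted time-series models with lagged-residual autocorrelation
    adjustment and overdispersion-scaled standard errors, and Poisson
    counterfactual estimates of absolute contact deficits per million persons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
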