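Package: avertr
Title: District-Level Counterfactual Estimates of Births Averted by Contraception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of births averted by contraceptive use at
    district, state and national level from survey-style birth-history
    microdata. Computes district total fertility rates (TFR) with Poisson
    delta-method confidence intervals directly from birth histories over a
    three-year reference window, contraceptive prevalence rates (CPR) among
    currently married women, fits pooled and stratified robust (Huber then
    bisquare IRLS) log-linear regressions of TFR on CPR, constructs the
    counterfactual "potential TFR" each district would experience with no
    contraceptive use, and derives births averted and the percentage increase
    in births with aggregation and sensitivity summaries. Includes a
    synthetic-data generator emulating DHS-style individual recode microdata
    so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
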