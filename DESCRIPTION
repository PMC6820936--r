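Package: stratprice
Title: Pricing and R&D Incentives for Biomarker-Stratified Treatments
    under Pay-for-Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves the sequential pricing game between a health authority
    that reimburses a new treatment under a pay-for-performance scheme and a
    pharmaceutical firm that may invest in R&D to find a predictive biomarker
    and stratify the patient population.  Provides closed-form equilibrium
    prices, the response-rate thresholds that partition the decision regimes,
    the firm's investment rule and R&D probability under a uniform
    investment-cost distribution, brute-force numerical verification of every
    closed form, Monte Carlo simulation of finite patient cohorts and
    replicated game play, a generator of admissible parameter scenarios, and
    configuration-driven sweep reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
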