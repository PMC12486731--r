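Package: ceafrontier
Title: Cost-Effectiveness Frontier Analysis for Group-Delivered Preventive
    Child Mental Health Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based cost-effectiveness analysis of alternative
    delivery strategies of a group cognitive-behavioural prevention programme
    for child anxiety and depression. Provides micro-costing of group delivery
    from resource quantities and unit costs, trapezoidal accumulation of
    repeated symptom and health-related quality of life measurements into
    accumulated scores and quality-adjusted life years (QALYs), incremental
    cost-effectiveness ratios (ICERs), cost-effectiveness frontier
    identification with strong and extended dominance, comparison against a
    willingness-to-pay threshold range, and a calibrated synthetic-trial
    generator (Gaussian copula with monotone dropout) so the full pipeline is
    testable without access to individual-level trial data.
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
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
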