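Package: fiscalspace
Title: Health Financing Panels and Decomposition of Government Health
    Expenditure Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing country-year health-financing panels in
    constant dollars: cohort filtering by population and data availability,
    start-of-period income grouping with large-country breakouts,
    expenditure-weighted (aggregate) versus country-weighted group
    indicators, endpoint percent-change and annualized compound growth
    rates, and a log-additive decomposition of growth in domestic
    government health expenditure into economic growth, expansion of
    government relative to GDP, and prioritization of health within the
    government budget. Includes benchmarking against the Abuja 15%-of-budget
    target and a 5%-of-GDP band, percentile-based outlier screening, a
    synthetic panel generator with recorded ground truth, and a one-call
    pipeline that writes table-ready reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
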