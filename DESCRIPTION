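Package: omppricer
Title: Cost-Based Pricing Models for Orphan Medicinal Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scenario engine for cost-based pricing of orphan medicinal
    products. Implements four pricing models used in health-technology
    assessment: a novel cancer pricing model (NCP), the AIM model for fair
    and transparent prices, a discounted-cash-flow break-even model (DCF),
    and a real-option rate-of-return model (ROROR). Supports minimum,
    maximum and averaged input scenarios, additive price breakdowns,
    one-at-a-time (tornado) sensitivity analysis, a fixed-population
    supplementary analysis, and a bundled case study of lumasiran for
    primary hyperoxaluria type 1. Results are returned as tibbles and can
    be plotted with ggplot2 or exported to CSV and JSON.
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
    tibble,
    tidyr,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
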