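Package: careflow
Title: Stock-and-Flow Projection of the Care Workforce
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic yearly stock-and-flow projection engine for
    planning the care workforce (Registered Nurses, Licensed Practical
    Nurses and Health Care Aides). Forecasts demand, supply, deficits and
    vacancy rates over a multi-year horizon from budgeted full-time
    equivalents, separation rates, graduate pipelines, population-growth
    schedules and economic-shock assumptions. Supports named policy
    scenarios expressed as parameter overrides, one-at-a-time sensitivity
    sweeps, a calibration mode that replays externally fixed demand and
    supply streams, and table, CSV, JSON and plot reporting.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
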