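Package: weeklymort
Title: Harmonization of Weekly Death Counts and Estimation of Excess Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw weekly all-cause death counts, as published
    by national statistical offices in heterogeneous age and sex groupings,
    into a harmonized table of deaths and person-week death rates in five
    standard age groups (0-14, 15-64, 65-74, 75-84, 85+) by sex. Unknown-age
    deaths are redistributed and broad age or combined-sex counts are split
    proportionally to annual death distributions; annual exposures missing for
    recent years are extrapolated with a Lee-Carter model under zero
    migration; weekly excess mortality is estimated against configurable
    reference baselines; and internal/external consistency checks produce a
    machine-readable validation report. A synthetic-data generator with known
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
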