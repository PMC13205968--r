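Package: betternest
Title: Household Environmental-Exposure Screening and the BetterNest Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores a nine-question household environmental-exposure screening
    instrument for pregnant women and parents. Converts survey responses plus
    county-level pre-1980 housing percentages and annual-average PM2.5
    concentrations into a 1.0-10.0 positive health index (higher = lower
    environmental risk) with the three highest-priority behavioral
    recommendations, rendered in non-judgmental, motivational-interviewing
    style language. Includes quintile/tertile risk banding of county
    surveillance data, a product-volume modifier matrix for the personal-care
    domain, a synthetic county-data fixture generator, an exhaustive
    enumerator certifying the attainable score range, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
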