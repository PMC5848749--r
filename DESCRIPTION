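Package: dietcost
Title: Diet Cost and Dietary Guideline Accordance from Linked Diary and
    Price Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links individual food-diary records to consumer price data to
    estimate the monetary cost of diets, scores diets against eight UK
    (SACN) food- and nutrient-based recommendations and an eight-component
    DASH accordance score (with residual-method energy adjustment), and
    estimates survey-weighted crude and covariate-adjusted mean diet costs
    with robust confidence intervals. Includes a synthetic-data generator
    that emulates 4-day unweighed diet diaries, scanner-panel price
    transactions and survey weights, with configurable ground-truth cost
    premiums for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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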