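Package: nppm
Title: Nutrient and Promotion Profile Model Assessment for Baby Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based assessment of commercially produced foods for infants
    and young children (under 36 months) against the WHO Regional Office for
    Europe's Nutrient and Promotion Profile Model (NPPM). Reads labelled
    product tables, applies the category-specific nutrient-composition
    criteria (energy density, protein, fat, total sugar as percent of energy,
    salt, added-sugar prohibition) and the promotional requirements (claims,
    age labels, breastfeeding statements, spout warnings, name clarity,
    ingredient-list completeness, preparation instructions, front-of-pack
    high-sugar flags), and aggregates per-product verdicts into category and
    age-band compliance tables, nutrient means with 95 percent confidence
    intervals per 100 g and per 100 kcal, and one-way ANOVA across
    categories. Includes a synthetic product generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
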