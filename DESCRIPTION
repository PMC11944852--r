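Package: adgat
Title: Australian Dietary Guidelines Adherence Tool for Food Frequency
    Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links food frequency questionnaire (FFQ) item definitions to a
    food composition database that carries dietary-guideline food-group
    servings per 100 g, using a rule-based string-matching pipeline
    (candidate search, exclusion criteria, not-further-defined and
    primary-position selection). Aggregates the surviving matches into a
    servings/100 g summary table per FFQ item, classifies items as
    discretionary when more than 20% of their matched foods carry the
    discretionary flag, quantifies discretionary servings as mean energy
    density divided by 600 kJ, and scores reported intakes (g/day) as food
    group servings/day for adherence evaluation against recommendation
    profiles. Ships the 101-item reference summary table for the Dietary
    Questionnaire for Epidemiological Studies and a seeded synthetic
    database generator so the whole pipeline is testable without external
    downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
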