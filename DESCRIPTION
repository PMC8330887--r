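Package: infodemic
Title: Infodemic Signal Detection from Social-Media Listening Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taxonomy-based social listening during public-health
    emergencies. Classifies public social-media posts into a keyword-defined
    public-health taxonomy via Boolean search strings, aggregates weekly
    per-topic volume, question presence and engagement, computes week-on-week
    velocity, flags potential information voids, and validates retrieval
    quality with precision, recall, F-scores and Cohen's kappa. Includes a
    seeded synthetic-corpus generator with ground-truth labels so every
    pipeline stage can be tested end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
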