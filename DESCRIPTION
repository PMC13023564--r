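Package: wswcat
Title: Social Categorization Analysis for Who-Said-What Memory-Confusion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring spontaneous social categorization with the
    Who-Said-What (WSW) memory-confusion paradigm. Builds balanced factorial
    face designs with exact combinatorial chance baselines, simulates trial-level
    recall cohorts from a cue-match softmax confusion model with known latent
    structure, computes per-participant within/between-category error scores and
    shared-feature overlap statistics, fits cue-interdependence regressions with
    simple slopes and nested-model comparisons, and separates genuine cue-based
    encoding from shared-error-pool artifacts with a constrained resampling null
    simulation.
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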