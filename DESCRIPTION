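Package: phenadapt
Title: Growth-Rate-Driven Modelling of Phenotypic Adaptation in Drug-Treated
    Cancer Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify phenotypic adaptation in drug-challenged cancer
    cell lines from cell-count data. Converts 72-hour fold-change assays into
    per-day net growth rates, assembles a phenotype-by-dose fitness matrix by
    linear interpolation between drug-naive and drug-adapted endpoints, and
    simulates a stochastic individual-based model in which cells move on a
    bounded phenotype lattice under four candidate update strategies (no
    update, unbiased, semi-biased, biased). Includes grid least-squares
    calibration of the four free treatment parameters against continuous and
    intermittent dosing curves, closed-form effective growth rates for
    periodic schedules derived from a piecewise-linear phenotype ODE, critical
    on/off interval computation, schedule heatmaps, and a synthetic-data
    generator with known ground truth for end-to-end testing.
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
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
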