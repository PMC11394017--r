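Package: dietshift
Title: Dietary-Shift Analysis of Paired Owl Pellet Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the diet spectrum of a raptor population
    between two paired pellet surveys. Reads long-format prey count tables,
    collapses mixed-rank prey identifications to a common taxonomic rank,
    normalises counts to per-pellet abundances, and computes Pielou evenness,
    Petraitis niche overlap, and feeding-guild abundance differences. The
    significance of each paired difference is assessed against a quantitative
    shuffle-and-swap permutation null model that conserves the grand total of
    prey individuals and the number of unexploited resource categories per
    survey, with non-parametric (probit) standardized effect sizes. Also
    provides non-metric multidimensional scaling of prey taxa on Euclidean
    distances of their per-pellet abundances, a Dirichlet-multinomial
    synthetic pellet-survey generator for calibration and power studies, and
    a single pipeline entry point producing publication-style result tables.
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
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
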