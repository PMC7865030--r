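Package: agedecomp
Title: Counterfactual Cohort-Component Projections and the Decomposition of Population Ageing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the demographic determinants of population
    ageing with counterfactual cohort-component population projections. The
    package projects single-year-of-age populations under four scenarios
    (actual rates; both vital rates fixed at base-year values; mortality
    fixed; fertility fixed), partitions the observed change in any ageing
    index into non-vital, fertility and mortality components with exact
    additivity, links fixed-rate projections to stable population theory
    (Euler-Lotka intrinsic growth rate, stable age distribution, relaxation
    times), estimates net migration by the balancing equation and
    age-specific fertility by indirect standardisation, reads and writes
    Human Mortality Database style files, and simulates demographic
    transition series for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
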