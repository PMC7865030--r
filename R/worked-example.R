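#' Published worked example: components of ageing in 11 European countries
#'
#' Loads the packaged worked-example table of counterfactual projection
#' outcomes for 11 European countries with long-run single-age data series:
#' percentage aged 65 and over in the base year 1900 and in the final year
#' (around 2015), the change under each of the four scenarios (actual, both
#' vital rates fixed, fertility fixed, mortality fixed — all with observed
#' net migration), and the published component shares. The change columns
#' are the inputs of [decompose_change()] (change-values, so `a0 = 0`); the
#' share columns are the published values the decomposition reproduces to
#' one-decimal rounding.
#'
#' @return Tibble with one row per country; columns `country`,
#'   `final_year`, `pct65_initial`, `pct65_final`, `change_actual`,
#'   `change_both_fixed`, `change_fertility_fixed`,
#'   `change_mortality_fixed`, `nonvital_pct`, `fertility_pct`,
#'   `mortality_pct`.
#' @examples
#' tab <- european_ageing_1900()
#' decompose_change(0, tab$change_actual, tab$change_both_fixed,
#'                  tab$change_mortality_fixed, tab$change_fertility_fixed,
#'                  index = "prop_65plus")
#' @export
european_ageing_1900 <- function() {
  path <- system.file("extdata", "european_ageing_1900.csv",
                      package = "agedecomp", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
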