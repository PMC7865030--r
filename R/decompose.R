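#' Decompose change in an ageing index into non-vital, fertility and
#' mortality components
#'
#' Partitions the observed change in any ageing index between a base time
#' and a later time, using the index values of the four counterfactual
#' scenarios at the later time. Writing \eqn{a^x} for the value of the index
#' under scenario \eqn{x} at the later time and \eqn{a_0} for the shared
#' base value:
#'
#' * vital component (joint effect of post-base fertility and mortality
#'   rates): \eqn{a^{Ac} - a^{Bf}};
#' * non-vital component (initial age structure and net migration):
#'   \eqn{a^{Bf} - a_0};
#' * mortality component: \eqn{0.5 (a^{Ac} - a^{Mf} + a^{Ff} - a^{Bf})},
#'   the average of the two available fixed-vs-actual mortality contrasts;
#' * fertility component: \eqn{0.5 (a^{Ac} - a^{Ff} + a^{Mf} - a^{Bf})}.
#'
#' These satisfy two exact additivity identities: fertility + mortality =
#' vital, and vital + non-vital = total observed change. Percentage shares
#' follow: the non-vital share of the actual change, and the fertility and
#' mortality shares of the vital component (which sum to 100 whenever the
#' vital component is non-zero).
#'
#' Inputs may be index *levels* at the later time (with `a0` the base-year
#' level) or, as in published summary tables, index *changes* since the base
#' year (then set `a0 = 0`); all components are differences, so the two
#' conventions agree.
#'
#' @param a0 Index value at the base time (0 when feeding change-values).
#' @param ac,bf,mf,ff Index values under scenarios Ac, Bf, Mf, Ff at the
#'   later time. All five arguments are vectorised.
#' @param index Optional index name(s) carried through to the output.
#' @param base_year,final_year Optional year labels carried through.
#' @return A tibble of class `ageing_decomposition`, one row per input
#'   element, with the component values, the scenario changes
#'   (`change_ac` .. `change_mf`), the percentage shares (`NA` with
#'   `shares_defined = FALSE` where the vital component is within 1e-9 of
#'   zero), and the year labels.
#' @examples
#' # a published worked row (change-values, so a0 = 0)
#' decompose_change(0, ac = 12.2, bf = -0.8, mf = 8.9, ff = 0.1)
#' @export
decompose_change <- function(a0, ac, bf, mf, ff, index = NA_character_,
                             base_year = NA_integer_, final_year = NA_integer_) {
  n <- max(lengths(list(a0, ac, bf, mf, ff)))
  vital <- ac - bf
  nonvital <- bf - a0
  actual <- ac - a0
  mortality <- 0.5 * (ac - mf + ff - bf)
  fertility <- 0.5 * (ac - ff + mf - bf)
  vital_ok <- abs(vital) > 1e-9
  actual_ok <- abs(actual) > 1e-9
  out <- tibble(
    index = rep_len(index, n),
    base_year = rep_len(base_year, n), final_year = rep_len(final_year, n),
    base_value = rep_len(a0, n),
    change_ac = rep_len(ac - a0, n), change_bf = rep_len(bf - a0, n),
    change_ff = rep_len(ff - a0, n), change_mf = rep_len(mf - a0, n),
    actual_change = rep_len(actual, n),
    vital_component = rep_len(vital, n),
    nonvital_component = rep_len(nonvital, n),
    mortality_component = rep_len(mortality, n),
    fertility_component = rep_len(fertility, n),
    nonvital_pct_of_actual = rep_len(ifelse(actual_ok, 100 * nonvital / actual, NA_real_), n),
    fertility_pct_of_vital = rep_len(ifelse(vital_ok, 100 * fertility / vital, NA_real_), n),
    mortality_pct_of_vital = rep_len(ifelse(vital_ok, 100 * mortality / vital, NA_real_), n),
    shares_defined = rep_len(vital_ok, n)
  )
  class(out) <- c("ageing_decomposition", class(out))
  out
}

#' Decompose a counterfactual scenario set at a given year
#'
#' Extracts the four scenario index values at `at_year` (any intermediate
#' year of the horizon, not only the final one) together with the shared
#' base-year value, and delegates to [decompose_change()].
#'
#' @param cf A `counterfactual_set` from [project_counterfactuals()].
#' @param index Name of the ageing index to decompose (must be among those
#'   evaluated in the set).
#' @param at_year Year at which to decompose (default: the final year).
#' @return An `ageing_decomposition` tibble (one row).
#' @export
decompose_scenarios <- function(cf, index = cf$indices[1],
                                at_year = cf$final_year) {
  stopifnot(inherits(cf, "counterfactual_set"))
  if (!index %in% cf$indices)
    abort(sprintf("index '%s' was not evaluated in this scenario set.", index))
  if (at_year < cf$base_year || at_year > cf$final_year)
    abort("`at_year` must lie within the projection horizon.")
  val <- function(sc, y) {
    s <- cf$scenarios[[sc]]
    if (is.null(s)) abort(sprintf("scenario %s is missing from the set.", sc))
    v <- s$index_series$value[s$index_series$index == index &
                                s$index_series$year == y]
    if (!length(v)) abort(sprintf("no %s value at year %d.", index, y))
    v
  }
  decompose_change(
    a0 = val("Ac", cf$base_year),
    ac = val("Ac", at_year), bf = val("Bf", at_year),
    mf = val("Mf", at_year), ff = val("Ff", at_year),
    index = index, base_year = cf$base_year, final_year = at_year
  )
}

#' Legacy baseline comparison alongside the corrected decomposition
#'
#' Earlier counterfactual studies attributed ageing to fertility or
#' mortality by comparing a single counterfactual trajectory directly with
#' the baseline value: \eqn{a^{Mf}(T) - a^{Ac}(0)} (mortality held fixed, so
#' read as the fertility-driven change) and \eqn{a^{Ff}(T) - a^{Ac}(0)}
#' (read as mortality-driven). Those contrasts also absorb the effect of the
#' initial age structure and migration; they approximate the corrected
#' components only when the initial structure is close to the stable
#' population of the base-year rates (so that \eqn{a^{Bf}(T) \approx
#' a^{Ac}(0)}). This helper returns both attributions side by side.
#'
#' @inheritParams decompose_scenarios
#' @return Tibble with the legacy attributions (`naive_fertility`,
#'   `naive_mortality`) and the corrected components.
#' @export
naive_comparison <- function(cf, index = cf$indices[1], at_year = cf$final_year) {
  d <- decompose_scenarios(cf, index, at_year)
  tibble(
    index = index, base_year = cf$base_year, at_year = at_year,
    naive_fertility = d$change_mf,
    naive_mortality = d$change_ff,
    fertility_component = d$fertility_component,
    mortality_component = d$mortality_component,
    nonvital_component = d$nonvital_component
  )
}

#' Averaged decomposition over sliding analysis windows
#'
#' Separates *influence time* (how long rates have been acting, i.e. the
#' projection launched at each base year) from *analysis time* (the window
#' over which index change is measured). For every base year `b` the four
#' scenarios are projected once to `max(final_years)`; for every final year
#' `y` the scenario index changes over the window — `span` years ending at
#' `y`, or the whole base-to-final interval when `span = "base"` — are
#' decomposed, and the component values are averaged over all admissible
#' (base, final) pairs with equal weight. Percentage shares are recomputed
#' from the averaged components.
#'
#' @param series A [vital_series()].
#' @param index Ageing index name.
#' @param base_years Integer vector of projection base years.
#' @param final_years Integer vector of candidate final years.
#' @param span Window length in years (e.g. `1` or `5`), or `"base"` for
#'   base-to-final windows.
#' @param migration Migration mode passed to [project_counterfactuals()].
#' @param initial Optional named list of initial populations per base year.
#' @return A one-row `ageing_decomposition` tibble with an extra `n_windows`
#'   column; `span` is recorded in place of single year labels.
#' @export
decompose_windowed <- function(series, index, base_years, final_years,
                               span = 1, migration = c("zero", "observed", "fixed"),
                               initial = NULL) {
  migration <- match.arg(migration)
  stopifnot(length(base_years) >= 1, length(final_years) >= 1)
  span_len <- if (identical(span, "base")) NA_integer_ else as.integer(span)
  rows <- purrr::map_dfr(base_years, function(b) {
    init_b <- if (is.null(initial)) NULL else initial[[as.character(b)]]
    cf <- project_counterfactuals(series, base_year = b,
                                  final_year = max(final_years),
                                  migration = migration, indices = index,
                                  initial = init_b)
    ser <- tidy(cf) |> filter(.data$index == !!index)
    v <- function(sc, y) ser$value[ser$scenario == sc & ser$year == y]
    ys <- final_years[final_years > b &
                        (is.na(span_len) | final_years - span_len >= b)]
    purrr::map_dfr(ys, function(y) {
      y0 <- if (is.na(span_len)) b else y - span_len
      decompose_change(0,
                       ac = v("Ac", y) - v("Ac", y0), bf = v("Bf", y) - v("Bf", y0),
                       mf = v("Mf", y) - v("Mf", y0), ff = v("Ff", y) - v("Ff", y0),
                       index = index, base_year = b, final_year = y)
    })
  })
  if (!nrow(rows)) abort("the window specification admits no (base, final) pairs.")
  comp <- rows |>
    summarise(across(c("change_ac", "change_bf", "change_ff", "change_mf",
                       "actual_change", "vital_component", "nonvital_component",
                       "mortality_component", "fertility_component"), mean))
  out <- decompose_change(0, ac = comp$change_ac, bf = comp$change_bf,
                          mf = comp$change_mf, ff = comp$change_ff,
                          index = index) |>
    mutate(span = if (is.na(span_len)) "base" else paste0(span_len, " year"),
           n_windows = nrow(rows))
  out
}

#' @export
print.ageing_decomposition <- function(x, ...) {
  cat("<ageing_decomposition>\n")
  NextMethod()
}

#' Long-format view of a decomposition
#'
#' @param x An `ageing_decomposition`.
#' @param ... Unused.
#' @return Tibble with one row per component per decomposition
#'   (`component`, `value`, `share_pct`).
#' @export
tidy.ageing_decomposition <- function(x, ...) {
  x |>
    mutate(.row = dplyr::row_number()) |>
    as_tibble() |>
    tidyr::pivot_longer(
      c("actual_change", "vital_component", "nonvital_component",
        "mortality_component", "fertility_component"),
      names_to = "component", values_to = "value") |>
    mutate(share_pct = dplyr::case_when(
      .data$component == "nonvital_component" ~ .data$nonvital_pct_of_actual,
      .data$component == "fertility_component" ~ .data$fertility_pct_of_vital,
      .data$component == "mortality_component" ~ .data$mortality_pct_of_vital,
      TRUE ~ NA_real_)) |>
    select("index", "base_year", "final_year", "component", "value", "share_pct")
}

#' @describeIn tidy.ageing_decomposition Compact per-decomposition summary.
#' @export
glance.ageing_decomposition <- function(x, ...) {
  as_tibble(x) |>
    select("index", "base_year", "final_year", "actual_change",
           "vital_component", "nonvital_component",
           "fertility_pct_of_vital", "mortality_pct_of_vital")
}

#' Bar chart of decomposition components
#'
#' @param object An `ageing_decomposition`.
#' @param ... Unused.
#' @return A ggplot with one bar per component.
#' @method autoplot ageing_decomposition
#' @export
autoplot.ageing_decomposition <- function(object, ...) {
  tidy(object) |>
    filter(.data$component != "actual_change") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contribution to index change")
}
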