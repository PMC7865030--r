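#' One-year cohort-component projection step
#'
#' Advances a single-year-of-age population one calendar year under given
#' fertility, central-mortality and net-migration schedules. Conventions:
#' survival uses `q = 1 - exp(-m)`; survivors of the cohort aged `a` at the
#' start of the year reach age `a + 1`, the open top interval accumulates
#' (`N'(A) = N(A-1)(1-q(A-1)) + N(A)(1-q(A))`, with `q(A)` taken from the
#' open-interval rate, not forced to 1); births `B = sum(f(a) N(a))` use the
#' start-of-year population and newborns face half a year of infant
#' mortality, `N'(0) = B (1 - 0.5 q(0))`; net migrants `M(a) N(a)` are added
#' after survival at the cohort's destination age and are exempt from
#' mortality in their year of arrival, with the birth cohort receiving
#' `newborn_migration * B` at age 0. Counts driven negative by large
#' negative migration rates are clipped to zero with a warning.
#'
#' @param counts Numeric vector of start-of-year counts by age `0 .. A`.
#' @param fertility,mortality Numeric vectors on the same ages (events per
#'   person-year; fertility is both-sexes-combined).
#' @param migration Optional numeric vector of net migration rates per
#'   start-of-year resident; `NULL` means a closed population.
#' @param newborn_migration Net migration rate of the in-year birth cohort,
#'   per birth (default 0).
#' @param detail If `TRUE`, return the full bookkeeping of the step.
#' @return With `detail = FALSE`, the end-of-year counts (equivalently the
#'   start of the next year). With `detail = TRUE`, a list with elements
#'   `counts`, `births`, `deaths` (cohort deaths by starting age),
#'   `newborn_deaths`, `migrants` (net migrant counts by starting age) and
#'   `newborn_migrants`.
#' @examples
#' project_step(c(100, 100, 100),
#'              fertility = c(0, 1, 0),
#'              mortality = probability_to_rate(c(0.1, 0.2, 0.5)))
#' @export
project_step <- function(counts, fertility, mortality, migration = NULL,
                         newborn_migration = 0, detail = FALSE) {
  n <- length(counts)
  if (length(fertility) != n || length(mortality) != n ||
      (!is.null(migration) && length(migration) != n))
    abort("`counts`, `fertility`, `mortality` and `migration` must share one age range.")
  if (any(counts < 0)) abort("population counts must be non-negative.")
  q <- rate_to_probability(mortality)
  deaths <- counts * q
  surv <- counts - deaths
  new <- numeric(n)
  new[2:n] <- surv[1:(n - 1L)]
  new[n] <- new[n] + surv[n]
  births <- sum(fertility * counts)
  nb_deaths <- 0.5 * q[1L] * births
  new[1L] <- births - nb_deaths

  migrants <- numeric(n)
  nb_migrants <- 0
  if (!is.null(migration)) {
    migrants <- migration * counts
    new[2:n] <- new[2:n] + migrants[1:(n - 1L)]
    new[n] <- new[n] + migrants[n]
    nb_migrants <- newborn_migration * births
    new[1L] <- new[1L] + nb_migrants
  }
  if (any(new < 0)) {
    warn(sprintf(
      "net out-migration exceeded the population at %d age(s); counts clipped to 0.",
      sum(new < 0)))
    new[new < 0] <- 0
  }
  if (!detail) return(new)
  list(counts = new, births = births, deaths = deaths,
       newborn_deaths = nb_deaths, migrants = migrants,
       newborn_migrants = nb_migrants)
}

scenario_modes <- function(scenario) {
  switch(scenario,
    Ac = list(fert_fixed = FALSE, mort_fixed = FALSE),
    Bf = list(fert_fixed = TRUE,  mort_fixed = TRUE),
    Mf = list(fert_fixed = FALSE, mort_fixed = TRUE),
    Ff = list(fert_fixed = TRUE,  mort_fixed = FALSE),
    abort("`scenario` must be one of 'Ac', 'Bf', 'Mf', 'Ff'.")
  )
}

#' Run one counterfactual projection scenario
#'
#' Iterates [project_step()] from `base_year` to `final_year`, with fertility
#' and mortality either following the observed series ("actual") or frozen at
#' their base-year schedules ("fixed"), according to the scenario code:
#'
#' * `"Ac"` — actual fertility, actual mortality;
#' * `"Bf"` — both fixed at base-year rates;
#' * `"Mf"` — mortality fixed, fertility actual;
#' * `"Ff"` — fertility fixed, mortality actual.
#'
#' Migration is treated separately: `"zero"` (closed population),
#' `"observed"` (the series' year-by-year net rates) or `"fixed"` (net rates
#' frozen at the base year — rates, not absolute numbers, since scenario
#' population sizes diverge).
#'
#' @param series A [vital_series()].
#' @param scenario One of `"Ac"`, `"Bf"`, `"Mf"`, `"Ff"`.
#' @param base_year,final_year Projection span (both inside the series;
#'   `final_year` defaults to the last series year).
#' @param migration One of `"zero"`, `"observed"`, `"fixed"`.
#' @param indices Character vector of ageing indices to evaluate along the
#'   trajectory; see [ageing_indices()].
#' @param initial Optional starting population: a data frame with `age` and
#'   `count`, or a numeric vector by age. Defaults to the series' stored
#'   population at `base_year`.
#' @return A `scenario_projection` object holding the population trajectory
#'   (matrix ages x years) and the index series; use [tidy()] for the index
#'   series and `population()`-style access via `$population`.
#' @export
project_scenario <- function(series, scenario = c("Ac", "Bf", "Mf", "Ff"),
                             base_year, final_year = max(series$years),
                             migration = c("zero", "observed", "fixed"),
                             indices = c("prop_65plus", "mean_age"),
                             initial = NULL) {
  stopifnot(inherits(series, "vital_series"))
  scenario <- match.arg(scenario)
  migration <- match.arg(migration)
  check_year_in(series, base_year, "base year")
  pop0 <- resolve_initial(series, base_year, initial)
  modes <- scenario_modes(scenario)
  # a horizon beyond the observed span is only meaningful when every
  # year-varying input is frozen (or absent)
  open_horizon <- modes$fert_fixed && modes$mort_fixed && migration != "observed"
  if (final_year <= base_year ||
      (!open_horizon && final_year > max(series$years) + 1L))
    abort(sprintf("`final_year` must lie in (base_year, %d].", max(series$years) + 1L))
  if (migration != "zero" && is.null(series$migration))
    abort("the series carries no migration rates; use migration = 'zero'.")

  yrs <- base_year:final_year
  nm <- length(series$ages)
  traj <- matrix(NA_real_, nrow = nm, ncol = length(yrs),
                 dimnames = list(series$ages, yrs))
  traj[, 1L] <- pop0
  f_base <- year_col(series$fertility, series$years, base_year)
  m_base <- year_col(series$mortality, series$years, base_year)
  for (k in seq_len(length(yrs) - 1L)) {
    t_now <- yrs[k]
    f <- if (modes$fert_fixed) f_base else year_col(series$fertility, series$years, t_now)
    m <- if (modes$mort_fixed) m_base else year_col(series$mortality, series$years, t_now)
    mig <- switch(migration,
      zero = NULL,
      observed = year_col(series$migration, series$years, t_now),
      fixed = year_col(series$migration, series$years, base_year))
    nb_mig <- switch(migration,
      zero = 0,
      observed = series$newborn_migration[[as.character(t_now)]],
      fixed = series$newborn_migration[[as.character(base_year)]])
    traj[, k + 1L] <- project_step(traj[, k], f, m, mig, nb_mig)
  }

  idx <- ageing_indices(as_pop_tbl(traj), indices = indices)
  structure(
    list(scenario = scenario, base_year = base_year, final_year = final_year,
         migration = migration, population = traj, index_series = idx,
         ages = series$ages),
    class = "scenario_projection"
  )
}

resolve_initial <- function(series, base_year, initial) {
  if (is.null(initial)) {
    pop0 <- series_population_at(series, base_year)
    if (is.null(pop0))
      abort(sprintf("the series has no stored population for %d; supply `initial`.", base_year))
    return(pop0)
  }
  if (is.data.frame(initial)) {
    stopifnot(all(c("age", "count") %in% names(initial)))
    initial <- initial$count[order(initial$age)]
  }
  if (length(initial) != length(series$ages))
    abort("`initial` must cover the series' full age range.")
  if (any(initial < 0)) abort("initial counts must be non-negative.")
  as.numeric(initial)
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat(sprintf("<scenario_projection> %s, %d-%d, migration = %s\n",
              x$scenario, x$base_year, x$final_year, x$migration))
  cat(sprintf("  indices: %s\n", paste(unique(x$index_series$index), collapse = ", ")))
  invisible(x)
}

#' @describeIn project_scenario Index series as a tibble
#'   (`scenario`, `year`, `index`, `value`).
#' @param x A `scenario_projection`.
#' @param ... Unused.
#' @export
tidy.scenario_projection <- function(x, ...) {
  mutate(x$index_series, scenario = x$scenario, .before = 1)
}

#' @describeIn project_scenario One-row summary with final index values.
#' @export
glance.scenario_projection <- function(x, ...) {
  fin <- x$index_series |> filter(.data$year == x$final_year) |>
    tidyr::pivot_wider(names_from = "index", values_from = "value",
                       names_prefix = "final_")
  tibble(scenario = x$scenario, base_year = x$base_year,
         final_year = x$final_year, migration = x$migration,
         total_final = sum(x$population[, ncol(x$population)])) |>
    bind_cols(select(fin, -"year"))
}

#' Run the four counterfactual scenarios as a set
#'
#' Batch driver producing the `Ac`, `Bf`, `Mf` and `Ff` trajectories from a
#' shared initial population, ready for [decompose_scenarios()].
#'
#' @inheritParams project_scenario
#' @return A `counterfactual_set`: list of the four `scenario_projection`
#'   objects plus the shared metadata.
#' @export
project_counterfactuals <- function(series, base_year,
                                    final_year = max(series$years),
                                    migration = c("zero", "observed", "fixed"),
                                    indices = c("prop_65plus", "mean_age"),
                                    initial = NULL) {
  migration <- match.arg(migration)
  initial <- resolve_initial(series, base_year, initial)
  runs <- purrr::map(
    setNames(c("Ac", "Bf", "Mf", "Ff"), c("Ac", "Bf", "Mf", "Ff")),
    function(sc) project_scenario(series, sc, base_year, final_year,
                                  migration, indices, initial = initial))
  structure(
    list(scenarios = runs, base_year = base_year, final_year = final_year,
         migration = migration, indices = indices),
    class = "counterfactual_set"
  )
}

#' @export
print.counterfactual_set <- function(x, ...) {
  cat(sprintf("<counterfactual_set> Ac/Bf/Mf/Ff, %d-%d, migration = %s\n",
              x$base_year, x$final_year, x$migration))
  invisible(x)
}

#' @describeIn project_counterfactuals All four index series in one tibble.
#' @param x A `counterfactual_set`.
#' @param ... Unused.
#' @export
tidy.counterfactual_set <- function(x, ...) {
  purrr::map_dfr(x$scenarios, tidy)
}

#' @describeIn project_counterfactuals One row per scenario.
#' @export
glance.counterfactual_set <- function(x, ...) {
  purrr::map_dfr(x$scenarios, glance)
}

#' Plot index trajectories of a counterfactual scenario set
#'
#' @param object A `counterfactual_set`.
#' @param ... Unused.
#' @return A ggplot: one panel per ageing index, one line per scenario.
#' @method autoplot counterfactual_set
#' @export
autoplot.counterfactual_set <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$value,
                                 colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "year", y = "index value", colour = "scenario")
}

#' @rdname project_scenario
#' @param object A `scenario_projection` (for `autoplot`).
#' @method autoplot scenario_projection
#' @export
autoplot.scenario_projection <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "year", y = "index value",
                  title = sprintf("Scenario %s", object$scenario))
}
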