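#' Assemble a vital-rate series for one population
#'
#' A `vital_series` bundles everything the projection engine needs for one
#' country (real or simulated): age-specific fertility, central mortality and
#' net-migration rate schedules for a contiguous run of years, together with
#' total births and, optionally, cohort deaths and start-of-year population
#' counts. Fertility follows the both-sexes-combined convention (births of
#' either sex per person-year of either sex).
#'
#' Rates are indexed by single year of age `0 .. a_max`, with the top age
#' open-ended ("`a_max` and over"). Migration rates are net rates per
#' start-of-year resident; the in-year birth cohort carries its own net rate
#' (per birth), coded as age `-1` in tidy input/output.
#'
#' @param rates Data frame with columns `year`, `age`, `fertility`,
#'   `mortality` and optionally `migration`; one row per year-age, covering a
#'   complete age range `0 .. a_max` for every year of a contiguous span of
#'   at least two years. Rows with `age == -1` supply the birth-cohort
#'   migration rate (their fertility/mortality entries are ignored).
#' @param births Optional data frame `year`, `births` (total annual births).
#' @param deaths Optional data frame `year`, `age`, `deaths` holding cohort
#'   deaths: deaths during year `t` of the cohort aged `a` at the start of
#'   `t`, with `age == -1` for deaths of the cohort born during the year.
#' @param population Optional data frame `year`, `age`, `count` of
#'   start-of-year population; may extend one year past the rate span.
#' @return An object of class `vital_series`.
#' @seealso [sim_transition_series()] to generate one,
#'   [assemble_vital_series()] to build one from HMD-style files,
#'   [project_scenario()] to project one.
#' @export
vital_series <- function(rates, births = NULL, deaths = NULL, population = NULL) {
  stopifnot(is.data.frame(rates))
  need <- c("year", "age", "fertility", "mortality")
  if (!all(need %in% names(rates)))
    abort("`rates` needs columns year, age, fertility, mortality (migration optional).")

  body_df <- rates[rates$age >= 0, , drop = FALSE]
  years <- sort(unique(as.integer(body_df$year)))
  if (length(years) < 2 || !all(diff(years) == 1L))
    abort("`rates` must cover a contiguous span of at least two years.")
  ages <- sort(unique(as.integer(body_df$age)))
  a_max <- max(ages)
  if (!identical(ages, 0:a_max))
    abort("`rates` must cover every single age 0..a_max.")

  to_mat <- function(col) {
    m <- matrix(NA_real_, nrow = a_max + 1L, ncol = length(years),
                dimnames = list(0:a_max, years))
    m[cbind(body_df$age + 1L, match(body_df$year, years))] <- body_df[[col]]
    if (anyNA(m)) abort(sprintf("column `%s` is missing for some year-age combinations.", col))
    m
  }
  fert <- to_mat("fertility")
  mort <- to_mat("mortality")
  mig <- if ("migration" %in% names(body_df)) to_mat("migration") else NULL

  if (any(fert < 0)) abort("fertility rates must be non-negative.")
  if (any(mort < 0)) abort("mortality rates must be non-negative.")
  if (any(mort[a_max + 1L, ] <= 0))
    abort("the open-interval mortality rate must be positive in every year.")

  nb_mig <- setNames(rep(0, length(years)), years)
  if (any(rates$age == -1) && "migration" %in% names(rates)) {
    nb <- rates[rates$age == -1, , drop = FALSE]
    nb_mig[as.character(nb$year)] <- nb$migration
  }

  births_vec <- NULL
  if (!is.null(births)) {
    stopifnot(is.data.frame(births), all(c("year", "births") %in% names(births)))
    births_vec <- setNames(births$births, births$year)[as.character(years)]
  }

  deaths_mat <- NULL
  nb_deaths <- NULL
  if (!is.null(deaths)) {
    stopifnot(is.data.frame(deaths), all(c("year", "age", "deaths") %in% names(deaths)))
    dd <- deaths[deaths$age >= 0, , drop = FALSE]
    deaths_mat <- matrix(NA_real_, nrow = a_max + 1L, ncol = length(years),
                         dimnames = list(0:a_max, years))
    deaths_mat[cbind(dd$age + 1L, match(dd$year, years))] <- dd$deaths
    nbd <- deaths[deaths$age == -1, , drop = FALSE]
    if (nrow(nbd)) nb_deaths <- setNames(nbd$deaths, nbd$year)[as.character(years)]
  }

  pop_mat <- NULL
  pop_years <- NULL
  if (!is.null(population)) {
    stopifnot(is.data.frame(population), all(c("year", "age", "count") %in% names(population)))
    pop_years <- sort(unique(as.integer(population$year)))
    pop_mat <- matrix(NA_real_, nrow = a_max + 1L, ncol = length(pop_years),
                      dimnames = list(0:a_max, pop_years))
    pop_mat[cbind(population$age + 1L, match(population$year, pop_years))] <- population$count
    if (any(pop_mat < 0, na.rm = TRUE)) abort("population counts must be non-negative.")
  }

  structure(
    list(ages = 0:a_max, a_max = a_max, years = years,
         fertility = fert, mortality = mort, migration = mig,
         newborn_migration = nb_mig, births = births_vec,
         deaths = deaths_mat, newborn_deaths = nb_deaths,
         population = pop_mat, pop_years = pop_years),
    class = "vital_series"
  )
}

# internal fast-path constructor used by the simulator (matrices already built)
new_vital_series <- function(years, fertility, mortality, migration = NULL,
                             newborn_migration = NULL, births = NULL,
                             deaths = NULL, newborn_deaths = NULL,
                             population = NULL, pop_years = NULL) {
  a_max <- nrow(fertility) - 1L
  structure(
    list(ages = 0:a_max, a_max = a_max, years = as.integer(years),
         fertility = fertility, mortality = mortality, migration = migration,
         newborn_migration = newborn_migration %||% setNames(rep(0, length(years)), years),
         births = births, deaths = deaths, newborn_deaths = newborn_deaths,
         population = population, pop_years = pop_years),
    class = "vital_series"
  )
}

#' @export
print.vital_series <- function(x, ...) {
  cat(sprintf("<vital_series> %d-%d, ages 0-%d+\n",
              min(x$years), max(x$years), x$a_max))
  cat(sprintf("  components: fertility, mortality%s%s%s%s\n",
              if (!is.null(x$migration)) ", migration" else "",
              if (!is.null(x$births)) ", births" else "",
              if (!is.null(x$deaths)) ", deaths" else "",
              if (!is.null(x$population)) ", population" else ""))
  invisible(x)
}

#' @describeIn vital_series Long tibble of the rate schedules
#'   (`year`, `age`, `fertility`, `mortality`, `migration`).
#' @param x A `vital_series`.
#' @param ... Unused.
#' @export
tidy.vital_series <- function(x, ...) {
  out <- tidyr::expand_grid(year = x$years, age = x$ages) |>
    mutate(
      fertility = as.vector(x$fertility[cbind(.data$age + 1L, match(.data$year, x$years))]),
      mortality = as.vector(x$mortality[cbind(.data$age + 1L, match(.data$year, x$years))]),
      migration = if (is.null(x$migration)) 0 else
        as.vector(x$migration[cbind(.data$age + 1L, match(.data$year, x$years))])
    )
  out
}

#' @describeIn vital_series One-row summary of the series.
#' @export
glance.vital_series <- function(x, ...) {
  tibble(
    first_year = min(x$years), last_year = max(x$years),
    n_years = length(x$years), a_max = x$a_max,
    has_migration = !is.null(x$migration),
    has_births = !is.null(x$births),
    has_population = !is.null(x$population)
  )
}

# --- internal accessors ------------------------------------------------------

year_col <- function(mat, years, year) mat[, match(year, years)]

series_population_at <- function(series, year) {
  if (is.null(series$population)) return(NULL)
  j <- match(year, series$pop_years)
  if (is.na(j)) return(NULL)
  series$population[, j]
}

check_year_in <- function(series, year, what) {
  if (!year %in% series$years)
    abort(sprintf("%s %d lies outside the series span %d-%d.",
                  what, year, min(series$years), max(series$years)))
}

#' Tidy a population matrix or age structure into a tibble
#'
#' @param counts Numeric vector of counts by age, or a matrix ages x years.
#' @param ages Integer ages (defaults to `0:(n-1)`).
#' @param years Optional year labels for matrix input.
#' @return Tibble with columns `age`, `count` (plus `year` for matrices).
#' @keywords internal
#' @noRd
as_pop_tbl <- function(counts, ages = NULL, years = NULL) {
  if (is.matrix(counts)) {
    ages <- ages %||% as.integer(rownames(counts))
    years <- years %||% as.integer(colnames(counts))
    tidyr::expand_grid(year = years, age = ages) |>
      mutate(count = as.vector(counts[cbind(match(.data$age, ages),
                                            match(.data$year, years))]))
  } else {
    tibble(age = ages %||% (0:(length(counts) - 1L)), count = as.numeric(counts))
  }
}
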