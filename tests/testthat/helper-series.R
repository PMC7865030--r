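# shared fixtures, built in code at test time

# short constant-rate series (near-stable start via the generator's burn-in)
constant_series <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_transition_series(years = 1900:1905, tfr = 2.5, e0 = 65)
    cache
  }
})

# compact transition series with a migration wave, shared across tests
demo_series <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_transition_series(
        years = 1900:1960, e0_start = 50, e0_end = 70, e0_midyear = 1925,
        tfr_start = 4, tfr_end = 1.9, tfr_midyear = 1930, tfr_width = 6,
        migration_events = list(list(years = 1905:1915, amplitude = -0.002)),
        seed = 42)
    cache
  }
})

# series with a sharp fertility drop at `drop_year`, constant mortality
fertility_drop_series <- function(years = 1900:1970, drop_year = 1935,
                                  high = 3.2, low = 1.9, e0 = 65) {
  tfr <- ifelse(years < drop_year, high, low)
  sim_transition_series(years = years, tfr = tfr, e0 = e0)
}

# cohort-deaths/births/population tibbles of a series, in estimator layout
series_tables <- function(s) {
  pop <- tidyr::expand_grid(year = s$pop_years, age = s$ages) |>
    dplyr::mutate(count = as.vector(s$population[cbind(age + 1L, match(year, s$pop_years))]))
  deaths <- dplyr::bind_rows(
    tidyr::expand_grid(year = s$years, age = s$ages) |>
      dplyr::mutate(deaths = as.vector(s$deaths[cbind(age + 1L, match(year, s$years))])),
    tibble::tibble(year = s$years, age = -1L, deaths = unname(s$newborn_deaths)))
  births <- tibble::tibble(year = s$years, births = unname(s$births))
  list(pop = pop, deaths = deaths, births = births)
}

delta_pop <- function(age, a_max = 110, total = 1e6) {
  v <- rep(0, a_max + 1L)
  v[age + 1L] <- total
  v
}
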