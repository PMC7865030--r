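#' Gompertz-Makeham mortality schedule
#'
#' Central death rates `m(a) = scale * (A + B * exp(c * a))`: a constant
#' background hazard `A` plus senescent mortality doubling every
#' `log(2)/c` years. Rates are capped at 20 per person-year so the
#' schedule stays finite at the open interval.
#'
#' @param a Makeham background hazard (`>= 0`).
#' @param b Gompertz level at age 0 (`> 0`).
#' @param c_rate Gompertz slope per year of age (`> 0`).
#' @param scale Overall level multiplier (`>= 0`); the simulator tunes this
#'   to hit a life-expectancy target.
#' @param ages Integer ages (default `0:110`).
#' @return Tibble with columns `age`, `mortality`.
#' @export
sim_mortality_schedule <- function(a = 2e-3, b = 7e-5, c_rate = 0.1,
                                   scale = 1, ages = 0:110) {
  if (b <= 0 || c_rate <= 0 || a < 0 || scale < 0)
    abort("need b > 0, c_rate > 0, a >= 0, scale >= 0.")
  m <- scale * (a + b * exp(c_rate * ages))
  if (any(!is.finite(m))) abort("parameters yield non-finite mortality rates.")
  tibble(age = as.integer(ages), mortality = pmin(m, 20))
}

#' Fertility schedule at a given total fertility rate
#'
#' Scales a standard age shape so the age-specific rates sum exactly to the
#' requested TFR (both-sexes convention): `f(a) = tfr * s(a)` with `s`
#' normalised to sum to one.
#'
#' @param tfr Total fertility rate (`>= 0`).
#' @param standard Standard shape from [standard_fertility()]; renormalised
#'   internally.
#' @param ages Ages used when `standard` is `NULL`.
#' @return Tibble with columns `age`, `fertility`.
#' @export
sim_fertility_schedule <- function(tfr, standard = NULL, ages = 0:110) {
  if (tfr < 0) abort("`tfr` must be non-negative.")
  std <- standard %||% standard_fertility(ages)
  std <- std[order(std$age), ]
  tibble(age = as.integer(std$age),
         fertility = tfr * std$weight / sum(std$weight))
}

logistic_path <- function(years, start, end, midyear, width) {
  start + (end - start) / (1 + exp(-(years - midyear) / width))
}

# tune the mortality scale multiplier so the schedule hits a target e0
solve_mortality_scale <- function(target_e0, a, b, c_rate, ages, year) {
  f <- function(log_s) {
    m <- sim_mortality_schedule(a, b, c_rate, exp(log_s), ages)$mortality
    life_expectancy(life_table(m)) - target_e0
  }
  lo <- log(1e-4); hi <- log(1e3)
  # below ~10 the Gompertz shape cannot bend enough; above 100 the solution
  # would live in the open interval's tail, not in the age range proper
  if (target_e0 < 10 || target_e0 > 100 || f(lo) < 0 || f(hi) > 0)
    abort(sprintf("life-expectancy target %.1f for year %d is unattainable under this mortality family.",
                  target_e0, year))
  exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Simulate a demographic-transition vital series
#'
#' Generates a complete, internally consistent country series shaped like a
#' long-run single-age data collection: age-specific fertility following a
#' declining TFR path, Gompertz-Makeham mortality whose level is tuned
#' year by year to an improving life-expectancy path, optional net-migration
#' shocks, and the populations, births and cohort deaths obtained by running
#' the package's own projection engine forward. Because the populations are
#' produced by [project_step()], the balancing-equation and
#' indirect-standardisation estimators recover the injected rates to
#' numerical precision — every pipeline stage is testable without external
#' data.
#'
#' The starting structure is the stable population of the first year's
#' rates, followed by `burn_in` years of projection at those rates, so the
#' labelled start year resembles a settled pre-transition population.
#'
#' @param years Integer span of the series (default `1850:2015`).
#' @param a_max Open top age (default 110).
#' @param tfr Optional numeric TFR path (length of `years` or scalar);
#'   defaults to a logistic decline from `tfr_start` to `tfr_end` centred on
#'   `tfr_midyear` with time-scale `tfr_width` years.
#' @param tfr_start,tfr_end,tfr_midyear,tfr_width Parameters of the default
#'   TFR path (children per person: 4.5 falling to 1.8, centred on 1930).
#' @param e0 Optional life-expectancy path (non-decreasing); defaults to a
#'   logistic rise from `e0_start` to `e0_end` centred on `e0_midyear`.
#' @param e0_start,e0_end,e0_midyear,e0_width Parameters of the default
#'   life-expectancy path (40 rising to 80 years, centred on 1920).
#' @param makeham Named vector `c(a=, b=, c=)` of Gompertz-Makeham shape
#'   parameters; only the overall scale is tuned to the `e0` path.
#' @param standard Standard fertility shape (default
#'   [standard_fertility()]).
#' @param migration_events List of events, each a list with `years`
#'   (integer vector), `amplitude` (net rate at the profile peak, may be
#'   negative) and optionally `mean`/`sd` of the Gaussian age profile
#'   (defaults 25 and 8 — a young-adult migration hump).
#' @param initial_total Population size at the start of burn-in.
#' @param burn_in Years of fixed-rate projection before the first labelled
#'   year.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   applied to the fertility and mortality schedules (default 0, i.e. the
#'   paths are hit exactly); independent seeded streams per component.
#' @param seed Integer seed making the series reproducible bit for bit.
#' @return A [vital_series()] carrying fertility, mortality, migration,
#'   births, cohort deaths (including the birth cohort) and start-of-year
#'   populations for `years` plus one further year.
#' @export
sim_transition_series <- function(years = 1850:2015, a_max = 110,
                                  tfr = NULL, tfr_start = 4.5, tfr_end = 1.8,
                                  tfr_midyear = 1930, tfr_width = 8,
                                  e0 = NULL, e0_start = 40, e0_end = 80,
                                  e0_midyear = 1920, e0_width = 25,
                                  makeham = c(a = 2e-3, b = 7e-5, c = 0.1),
                                  standard = NULL,
                                  migration_events = list(),
                                  initial_total = 1e6, burn_in = 150,
                                  noise_sd = 0, seed = NULL) {
  years <- as.integer(years)
  ny <- length(years)
  ages <- 0:a_max
  na <- a_max + 1L
  if (ny < 2) abort("`years` must span at least two years.")
  tfr <- rep_len(tfr %||% logistic_path(years, tfr_start, tfr_end, tfr_midyear, tfr_width), ny)
  e0 <- rep_len(e0 %||% logistic_path(years, e0_start, e0_end, e0_midyear, e0_width), ny)
  if (any(tfr <= 0)) abort("the TFR path must be positive.")
  if (any(diff(e0) < -1e-9)) abort("the life-expectancy path must be non-decreasing.")
  std <- standard %||% standard_fertility(ages)

  fert <- matrix(0, na, ny, dimnames = list(ages, years))
  mort <- matrix(0, na, ny, dimnames = list(ages, years))
  for (j in seq_len(ny)) {
    s <- solve_mortality_scale(e0[j], makeham["a"], makeham["b"], makeham["c"],
                               ages, years[j])
    mort[, j] <- sim_mortality_schedule(makeham["a"], makeham["b"], makeham["c"],
                                        s, ages)$mortality
    fert[, j] <- sim_fertility_schedule(tfr[j], std)$fertility
  }

  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when noise_sd > 0.")
    fert <- fert * noise_matrix(seed + 1L, noise_sd, na, ny)
    mort <- mort * noise_matrix(seed + 2L, noise_sd, na, ny)
    mort[na, ] <- pmax(mort[na, ], 1e-8)  # keep the open interval closable
  }

  mig <- matrix(0, na, ny, dimnames = list(ages, years))
  for (ev in migration_events) {
    mean_a <- ev$mean %||% 25
    sd_a <- ev$sd %||% 8
    profile <- dnorm(ages, mean_a, sd_a) / dnorm(mean_a, mean_a, sd_a)
    j <- match(intersect(ev$years, years), years)
    mig[, j] <- mig[, j] + ev$amplitude * profile
  }

  # burn-in at the first year's rates from that year's stable structure
  lt1 <- life_table(mort[, 1L])
  r1 <- lotka_r(fert[, 1L], lt1)
  pop <- stable_age_distribution(r1, lt1)$share * initial_total
  for (k in seq_len(burn_in)) pop <- project_step(pop, fert[, 1L], mort[, 1L])

  popm <- matrix(NA_real_, na, ny + 1L, dimnames = list(ages, c(years, max(years) + 1L)))
  births <- setNames(numeric(ny), years)
  deaths <- matrix(NA_real_, na, ny, dimnames = list(ages, years))
  nb_deaths <- setNames(numeric(ny), years)
  popm[, 1L] <- pop
  for (j in seq_len(ny)) {
    st <- project_step(popm[, j], fert[, j], mort[, j], mig[, j],
                       newborn_migration = 0, detail = TRUE)
    popm[, j + 1L] <- st$counts
    births[j] <- st$births
    deaths[, j] <- st$deaths
    nb_deaths[j] <- st$newborn_deaths
  }

  new_vital_series(
    years = years, fertility = fert, mortality = mort, migration = mig,
    births = births, deaths = deaths, newborn_deaths = nb_deaths,
    population = popm, pop_years = c(years, max(years) + 1L)
  )
}

noise_matrix <- function(seed, sd, nr, nc) {
  old <- .Random.seed_safe()
  on.exit(restore_seed(old))
  set.seed(seed %% .Machine$integer.max)
  matrix(exp(rnorm(nr * nc, 0, sd)), nr, nc)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
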