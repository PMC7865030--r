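#' Standard age schedule of fertility
#'
#' A smooth unimodal weight schedule over the reproductive ages 15-49 with a
#' peak near age 28, normalised to sum to one. It is the default standard
#' used by indirect standardisation ([estimate_fertility_indirect()]) and by
#' the simulator's fertility schedules; any non-negative schedule with the
#' same layout can be supplied instead. The shape is a Beta(3, 4.39) density
#' over the reproductive span, evaluated at age midpoints.
#'
#' @param ages Integer ages of the full age range (default `0:110`).
#' @param range Reproductive age range as `c(low, high)` (default 15-49).
#' @param shape1,shape2 Beta shape parameters of the curve.
#' @return Tibble with columns `age`, `weight` (`sum(weight) == 1`).
#' @export
standard_fertility <- function(ages = 0:110, range = c(15, 49),
                               shape1 = 3, shape2 = 4.39) {
  w <- numeric(length(ages))
  in_range <- ages >= range[1] & ages <= range[2]
  u <- (ages[in_range] + 0.5 - range[1]) / (range[2] + 1 - range[1])
  w[in_range] <- stats::dbeta(u, shape1, shape2)
  tibble(age = as.integer(ages), weight = w / sum(w))
}

#' Estimate age-specific fertility by indirect standardisation
#'
#' Scales a standard fertility age schedule so that, applied to the observed
#' population, it reproduces the observed total births exactly:
#' `k(t) = B(t) / sum(s(a) N(a, t))` and `f(a, t) = k(t) s(a)`. Only the
#' level of fertility varies over time; the age shape is that of the
#' standard (a per-year list of standards may be given when the shape itself
#' should vary).
#'
#' @param pop Population data frame with columns `age`, `count` and
#'   optionally `year` (start-of-year population).
#' @param births Either a single total-births number (when `pop` has no
#'   `year` column) or a data frame `year`, `births`.
#' @param standard A standard schedule as from [standard_fertility()]
#'   (columns `age`, `weight`), or a named list of such schedules keyed by
#'   year. Weights are renormalised internally, which leaves the fitted
#'   rates unchanged.
#' @return Tibble with columns (`year`,) `age`, `fertility`. By
#'   construction `sum(fertility * count) == births` in every year.
#' @export
estimate_fertility_indirect <- function(pop, births, standard = NULL) {
  stopifnot(is.data.frame(pop), all(c("age", "count") %in% names(pop)))
  one <- function(df, B, std) {
    std <- std[order(std$age), ]
    df <- df[order(df$age), ]
    if (!identical(as.integer(std$age), as.integer(df$age)))
      abort("`standard` and `pop` must share the same age range.")
    if (any(std$weight < 0)) abort("standard weights must be non-negative.")
    expo <- sum(std$weight * df$count)
    if (expo <= 0) abort("zero standardised exposure; fertility level undefined.")
    tibble(age = df$age, fertility = (B / expo) * std$weight)
  }
  if ("year" %in% names(pop)) {
    stopifnot(is.data.frame(births), all(c("year", "births") %in% names(births)))
    years <- intersect(unique(pop$year), births$year)
    if (!length(years)) abort("`pop` and `births` share no years.")
    purrr::map_dfr(years, function(y) {
      std <- resolve_standard(standard, y, pop$age[pop$year == y])
      one(pop[pop$year == y, ], births$births[births$year == y][1], std) |>
        mutate(year = y, .before = 1)
    })
  } else {
    stopifnot(is.numeric(births), length(births) == 1)
    std <- resolve_standard(standard, NULL, pop$age)
    one(pop, births, std)
  }
}

resolve_standard <- function(standard, year, ages) {
  if (is.null(standard)) return(standard_fertility(sort(unique(ages))))
  if (is.data.frame(standard)) return(standard)
  if (is.list(standard) && !is.null(year)) {
    std <- standard[[as.character(year)]]
    if (is.null(std)) abort(sprintf("no standard schedule supplied for year %s.", year))
    return(std)
  }
  abort("`standard` must be a data frame or a per-year named list of data frames.")
}

#' Estimate net migration by the balancing equation
#'
#' Recovers net migration residually from population change, cohort deaths
#' and births: for the cohort aged `a` at the start of year `t`,
#' `M(a, t) = N(a+1, t+1) - N(a, t) + D(a, t)`, and for the cohort born
#' during the year `M(birth, t) = N(0, t+1) - B(t) + D(birth, t)`. Counts
#' are converted to rates on the start-of-year population (births for the
#' newborn cohort). This is the exact inverse of the migration step of
#' [project_step()] on engine-generated data.
#'
#' The two cohorts that land in the open top interval (ages `a_max - 1` and
#' `a_max`) cannot be separated by the balancing equation; their pooled net
#' rate is returned for both ages.
#'
#' @param pop Start-of-year population data frame `year`, `age`, `count`;
#'   estimates are produced for every year whose successor is also present.
#' @param deaths Cohort deaths data frame `year`, `age`, `deaths` (deaths in
#'   year `t` of the cohort aged `a` at the start of `t`), with `age == -1`
#'   rows for the in-year birth cohort when available.
#' @param births Data frame `year`, `births`.
#' @param mortality Optional rates data frame `year`, `age`, `mortality`,
#'   used only to default missing birth-cohort deaths to
#'   `0.5 * q(0, t) * B(t)` (the engine's newborn half-year exposure).
#' @return Tibble with columns `year`, `age` (`-1` = birth cohort), `count`
#'   (net migrants), `rate`, and `defined` (`FALSE` where the start-of-year
#'   denominator is zero, in which case `rate` is `NA` but `count` is kept).
#' @export
estimate_net_migration <- function(pop, deaths, births, mortality = NULL) {
  stopifnot(is.data.frame(pop), all(c("year", "age", "count") %in% names(pop)),
            is.data.frame(deaths), all(c("year", "age", "deaths") %in% names(deaths)),
            is.data.frame(births), all(c("year", "births") %in% names(births)))
  years <- sort(unique(pop$year))
  est_years <- years[(years + 1L) %in% years]
  est_years <- intersect(est_years, intersect(deaths$year, births$year))
  if (!length(est_years)) abort("no year has population at t and t+1 plus deaths and births.")

  ages <- sort(unique(pop$age))
  a_max <- max(ages)
  purrr::map_dfr(est_years, function(y) {
    N0 <- pop$count[pop$year == y][order(pop$age[pop$year == y])]
    N1 <- pop$count[pop$year == y + 1L][order(pop$age[pop$year == y + 1L])]
    d <- deaths[deaths$year == y, ]
    D <- setNames(rep(0, a_max + 1L), 0:a_max)
    D[as.character(d$age[d$age >= 0])] <- d$deaths[d$age >= 0]
    B <- births$births[births$year == y][1]

    Db <- d$deaths[d$age == -1]
    if (!length(Db)) {
      if (!is.null(mortality)) {
        m0 <- mortality$mortality[mortality$year == y & mortality$age == 0][1]
        Db <- 0.5 * rate_to_probability(m0) * B
      } else Db <- 0
    }

    # cohorts 0 .. a_max-2 arrive at single ages 1 .. a_max-1
    a_lo <- 0:(a_max - 2L)
    cnt <- N1[a_lo + 2L] - N0[a_lo + 1L] + D[a_lo + 1L]
    # cohorts a_max-1 and a_max pool into the open interval
    top_cnt <- N1[a_max + 1L] - (N0[a_max] + N0[a_max + 1L]) +
      D[a_max] + D[a_max + 1L]
    top_base <- N0[a_max] + N0[a_max + 1L]
    nb_cnt <- N1[1L] - B + Db

    base <- c(B, N0[a_lo + 1L], rep(top_base, 2L))
    top_split <- if (top_base > 0) {
      top_cnt * c(N0[a_max], N0[a_max + 1L]) / top_base
    } else c(0, top_cnt)  # denominator empty: keep the pooled count
    count <- unname(c(nb_cnt, cnt, top_split))
    base <- unname(base)
    tibble(year = y, age = c(-1L, a_lo, a_max - 1L, a_max),
           count = count, rate = ifelse(base > 0, count / base, NA_real_),
           defined = base > 0)
  })
}
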