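test_that("a pure-ageing step shifts cohorts and accumulates the top interval", {
  out <- project_step(c(100, 100, 100), fertility = rep(0, 3),
                      mortality = c(0, 0, probability_to_rate(0.999999)))
  # survivors of the open interval remain (q(top) from its rate, not forced to 1)
  expect_equal(out[1:2], c(0, 100))
  expect_equal(out[3], 100 + 100 * (1 - 0.999999))
  out0 <- project_step(c(100, 100, 100), rep(0, 3), c(0, 0, 1e-12))
  expect_equal(out0, c(0, 100, 200), tolerance = 1e-9)
})

test_that("the worked one-year step reproduces hand cohort arithmetic", {
  q <- c(0.1, 0.2, 0.5)
  st <- project_step(c(100, 100, 100), fertility = c(0, 1, 0),
                     mortality = probability_to_rate(q), detail = TRUE)
  expect_equal(st$births, 100)
  expect_equal(st$counts, c(95, 90, 130))  # B(1-0.5q0); 100*0.9; 100*0.8+100*0.5
  expect_equal(st$deaths, c(10, 20, 50))
  expect_equal(st$newborn_deaths, 5)
})

test_that("closed-population bookkeeping balances exactly", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    N <- stats::runif(n, 0, 1000)
    f <- c(0, stats::runif(n - 2, 0, 0.2), 0)
    m <- stats::rgamma(n, 0.5, 10) + 1e-8
    q <- rate_to_probability(m)
    out <- project_step(N, f, m)
    B <- sum(f * N)
    expect_equal(sum(out), sum(N * (1 - q)) + B * (1 - 0.5 * q[1]),
                 tolerance = 1e-12)
  }
})

test_that("mismatched age ranges and negative counts are rejected", {
  expect_error(project_step(c(1, 2), c(0, 0, 0), c(0, 0, 1)), "share one age range")
  expect_error(project_step(c(-1, 2), c(0, 0), c(0, 1)), "non-negative")
})

test_that("excess out-migration clips to zero with a warning", {
  expect_warning(
    out <- project_step(c(10, 10, 10), rep(0, 3), c(0, 0, 0.5),
                        migration = c(-2, 0, 0)),
    "clipped")
  expect_true(all(out >= 0))
})

test_that("scenario Ac with observed migration reproduces the generator's populations", {
  s <- demo_series()
  run <- project_scenario(s, "Ac", min(s$years), max(s$years) + 1L,
                          migration = "observed")
  expect_lt(max(abs(run$population - s$population)), 1e-9)
})

test_that("all four scenarios share the base-year index value", {
  s <- demo_series()
  cf <- project_counterfactuals(s, 1920, 1955, migration = "observed",
                                indices = c("prop_65plus", "mean_age"))
  base_vals <- tidy(cf) |>
    dplyr::filter(.data$year == 1920) |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(spread = diff(range(.data$value)))
  expect_true(all(base_vals$spread == 0))
})

test_that("with constant rates the four scenario trajectories coincide", {
  s <- constant_series()
  cf <- project_counterfactuals(s, 1900, 1905, migration = "zero")
  ref <- cf$scenarios$Ac$population
  for (sc in c("Bf", "Mf", "Ff"))
    expect_equal(cf$scenarios[[sc]]$population, ref, tolerance = 1e-12)
})

test_that("fixing fertility at a pre-drop base ages the population faster than actual rates", {
  s <- fertility_drop_series()
  cf <- project_counterfactuals(s, 1920, 1970, migration = "zero",
                                indices = "prop_65plus")
  fin <- tidy(cf) |> dplyr::filter(.data$year == 1970)
  v <- setNames(fin$value, fin$scenario)
  # fertility frozen at the high pre-drop level keeps the population younger
  expect_lt(v["Ff"], v["Ac"])
  # and the actual fertility decline dominates what mortality-fixing removes
  expect_gt(v["Mf"], v["Bf"])
})

test_that("zero-migration scenarios ignore the migration schedules entirely", {
  s <- demo_series()
  s_nom <- s
  s_nom$migration <- NULL
  r1 <- project_scenario(s, "Bf", 1910, 1950, migration = "zero")
  r2 <- project_scenario(s_nom, "Bf", 1910, 1950, migration = "zero")
  expect_identical(r1$population, r2$population)
})

test_that("actual-rate scenarios refuse horizons beyond the observed span", {
  s <- constant_series()
  expect_error(project_scenario(s, "Ac", 1900, 1990), "final_year")
  expect_error(project_scenario(s, "Bf", 1890, 1990), "outside the series")
  expect_silent(project_scenario(s, "Bf", 1900, 1990, migration = "zero"))
})

test_that("weak ergodicity: extreme initial structures converge under fixed rates", {
  s <- constant_series()
  young <- delta_pop(0)
  old <- delta_pop(49)  # top of the reproductive span; older structures bear no births
  r1 <- project_scenario(s, "Bf", 1900, 2300, migration = "zero", initial = young,
                         indices = "mean_age")
  r2 <- project_scenario(s, "Bf", 1900, 2300, migration = "zero", initial = old,
                         indices = "mean_age")
  gap <- function(k) {
    p1 <- r1$population[, k] / sum(r1$population[, k])
    p2 <- r2$population[, k] / sum(r2$population[, k])
    max(abs(p1 - p2))
  }
  g <- vapply(c(101, 201, 301, 401), gap, numeric(1))
  expect_true(all(diff(g) < 0))   # sup-norm difference decays
  expect_lt(g[4], 1e-6)           # and is below 1e-6 beyond year 300
})

test_that("a fixed-rate zero-migration run stops ageing", {
  s <- constant_series()
  run <- project_scenario(s, "Bf", 1900, 2300, migration = "zero",
                          indices = c("prop_65plus", "mean_age"))
  late <- run$index_series |>
    dplyr::filter(.data$year >= 2290) |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(dmax = max(abs(diff(.data$value))))
  expect_true(all(late$dmax < 1e-8))
})
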