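test_that("a published worked row decomposes to the printed shares", {
  # Denmark, base 1900: changes Ac 12.1, Bf -1.7, Ff -0.6, Mf 8.4
  d <- decompose_change(0, ac = 12.1, bf = -1.7, mf = 8.4, ff = -0.6)
  expect_equal(d$vital_component, 13.8)
  expect_equal(round(d$fertility_pct_of_vital, 1), 82.6)
  expect_equal(round(d$mortality_pct_of_vital, 1), 17.4)
  expect_equal(d$fertility_pct_of_vital + d$mortality_pct_of_vital, 100)
})

test_that("additivity identities hold to machine precision for random inputs", {
  set.seed(505)
  a0 <- stats::runif(500, -5, 15); ac <- stats::runif(500, -5, 15)
  bf <- stats::runif(500, -5, 15); mf <- stats::runif(500, -5, 15)
  ff <- stats::runif(500, -5, 15)
  d <- decompose_change(a0, ac, bf, mf, ff)
  expect_lt(max(abs(d$fertility_component + d$mortality_component -
                      d$vital_component)), 1e-12)
  expect_lt(max(abs(d$vital_component + d$nonvital_component -
                      d$actual_change)), 1e-12)
  ok <- d$shares_defined
  expect_lt(max(abs(d$fertility_pct_of_vital[ok] +
                      d$mortality_pct_of_vital[ok] - 100)), 1e-9)
})

test_that("swapping the Mf and Ff inputs swaps the fertility and mortality components", {
  d1 <- decompose_change(1, ac = 9, bf = 2, mf = 7, ff = 4)
  d2 <- decompose_change(1, ac = 9, bf = 2, mf = 4, ff = 7)
  expect_equal(d1$fertility_component, d2$mortality_component)
  expect_equal(d1$mortality_component, d2$fertility_component)
  expect_equal(d1$vital_component, d2$vital_component)
})

test_that("identical scenario values give zero vital components and undefined shares", {
  d <- decompose_change(3, ac = 5, bf = 5, mf = 5, ff = 5)
  expect_equal(d$vital_component, 0)
  expect_equal(d$fertility_component, 0)
  expect_equal(d$mortality_component, 0)
  expect_equal(d$nonvital_component, 2)
  expect_false(d$shares_defined)
  expect_true(is.na(d$fertility_pct_of_vital))
})

test_that("decomposing at the base year returns all-zero components", {
  s <- constant_series()
  cf <- project_counterfactuals(s, 1900, 1905, migration = "zero")
  d <- decompose_scenarios(cf, "prop_65plus", at_year = 1900)
  expect_equal(d$actual_change, 0)
  expect_equal(d$vital_component, 0)
  expect_equal(d$nonvital_component, 0)
})

test_that("constant rates put the whole change in the non-vital component", {
  s <- constant_series()
  cf <- project_counterfactuals(s, 1900, 1905, migration = "zero",
                                indices = "mean_age")
  d <- decompose_scenarios(cf, "mean_age")
  expect_equal(d$fertility_component, 0, tolerance = 1e-12)
  expect_equal(d$mortality_component, 0, tolerance = 1e-12)
  expect_equal(d$nonvital_component, d$actual_change, tolerance = 1e-12)
})

test_that("a mortality-only transition loads the vital component on mortality", {
  s <- sim_transition_series(years = 1900:1950, tfr = 2.5,
                             e0 = seq(55, 70, length.out = 51))
  cf <- project_counterfactuals(s, 1900, 1950, migration = "zero",
                                indices = "prop_65plus")
  d <- decompose_scenarios(cf, "prop_65plus")
  expect_lt(abs(d$fertility_component), 0.05 * abs(d$vital_component))
  expect_equal(d$mortality_component, d$vital_component,
               tolerance = 0.05)
})

test_that("components are not transitive across adjoining intervals", {
  s <- fertility_drop_series(years = 1900:1960, drop_year = 1930)
  comp <- function(b, y) {
    cf <- project_counterfactuals(s, b, y, migration = "zero",
                                  indices = "prop_65plus")
    decompose_scenarios(cf, "prop_65plus")
  }
  d_whole <- comp(1910, 1950)
  d_a <- comp(1910, 1930)
  d_b <- comp(1930, 1950)
  expect_gt(abs(d_a$fertility_component + d_b$fertility_component -
                  d_whole$fertility_component), 0.1)
})

test_that("the dominant driver flips with the base year around a fertility drop", {
  s <- fertility_drop_series(years = 1900:1990, drop_year = 1935,
                             e0 = seq(60, 75, length.out = 91))
  share <- function(b) {
    cf <- project_counterfactuals(s, b, 1990, migration = "zero",
                                  indices = "prop_65plus")
    decompose_scenarios(cf, "prop_65plus")$fertility_pct_of_vital
  }
  expect_gt(share(1930), 50)  # fertility frozen at the high pre-drop level
  expect_lt(share(1940), 50)  # post-drop base: mortality improvement dominates
  expect_gt(share(1930), share(1940))
})

test_that("legacy baseline comparisons agree with the corrected components only from a stable start", {
  s <- sim_transition_series(years = 1900:1950, tfr = 2.5,
                             e0 = seq(55, 70, length.out = 51))
  # stable start: the generator's burnt-in structure is the base-year stable population
  cf_stable <- project_counterfactuals(s, 1900, 1950, migration = "zero",
                                       indices = "prop_65plus")
  nc <- naive_comparison(cf_stable, "prop_65plus")
  expect_lt(abs(nc$nonvital_component), 0.2)
  expect_equal(nc$naive_fertility, nc$fertility_component, tolerance = 0.2)
  expect_equal(nc$naive_mortality, nc$mortality_component, tolerance = 0.2)

  # young start under the same rates: corrected components are unchanged in
  # spirit but the legacy contrasts absorb the momentum of the structure
  young <- delta_pop(20) + delta_pop(0) + delta_pop(10)
  cf_young <- project_counterfactuals(s, 1900, 1950, migration = "zero",
                                      indices = "prop_65plus", initial = young)
  ncy <- naive_comparison(cf_young, "prop_65plus")
  expect_gt(abs(ncy$naive_fertility - ncy$fertility_component), 1)
  expect_gt(abs(ncy$nonvital_component), 1)
})

test_that("windowed decomposition reduces to the plain one for a single base-to-final window", {
  s <- demo_series()
  d_win <- decompose_windowed(s, "prop_65plus", base_years = 1910,
                              final_years = 1950, span = "base",
                              migration = "zero")
  cf <- project_counterfactuals(s, 1910, 1950, migration = "zero",
                                indices = "prop_65plus")
  d <- decompose_scenarios(cf, "prop_65plus")
  for (col in c("actual_change", "vital_component", "nonvital_component",
                "mortality_component", "fertility_component"))
    expect_equal(d_win[[col]], d[[col]], tolerance = 1e-12)
  expect_equal(d_win$n_windows, 1)
})

test_that("windowed vital components vanish under constant rates", {
  s <- constant_series()
  d <- decompose_windowed(s, "mean_age", base_years = 1900,
                          final_years = 1902:1905, span = 1,
                          migration = "zero")
  expect_equal(d$vital_component, 0, tolerance = 1e-12)
})

test_that("short analysis windows isolate post-base rates better than base-to-final spans", {
  # fertility falls before the base year, mortality improves after it: the
  # base-to-final window still carries the pre-base structure, the 1-year
  # windows do not
  years <- 1900:1980
  tfr <- ifelse(years < 1935, 3.5, 2.0)
  s <- sim_transition_series(years = years, tfr = tfr,
                             e0 = c(rep(60, 41), seq(60, 72, length.out = 40)))
  base <- 1941
  finals <- 1960:1980
  d1 <- decompose_windowed(s, "prop_65plus", base, finals, span = 1,
                           migration = "zero")
  db <- decompose_windowed(s, "prop_65plus", base, finals, span = "base",
                           migration = "zero")
  rel_nonvital <- function(d) abs(d$nonvital_component) /
    (abs(d$nonvital_component) + abs(d$vital_component))
  expect_gt(rel_nonvital(db), rel_nonvital(d1))
})
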