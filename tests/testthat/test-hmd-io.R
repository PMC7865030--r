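write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("the reader parses the dialect: sex columns, open age, missing values", {
  path <- write_lines_tmp(c(
    "Demo, Death rates (period 1x1)", "",
    "Year  Age  Female  Male  Total",
    "1850  0    0.12340 0.15670 0.13990",
    "1850  110+ 0.5     0.6     0.55",
    "1851  0    .       .       ."))
  expect_warning(tb <- read_hmd_table(path, "rates_1x1"), "1 missing")
  expect_equal(tb$total[tb$year == 1850 & tb$age == 0], 0.1399)
  expect_equal(tb$age[2], 110)
  expect_true(tb$open[2])
  expect_true(is.na(tb$total[tb$year == 1851]))
  expect_equal(attr(tb, "n_missing"), 1)
})

test_that("malformed rows and labels fail with their line number", {
  path <- write_lines_tmp(c("t", "", "Year Age Total", "1850 0 0.1 0.2"))
  expect_error(read_hmd_table(path, "rates_1x1"), "line 4")
  path2 <- write_lines_tmp(c("t", "", "Year Age Total", "1850 young 0.1"))
  expect_error(read_hmd_table(path2, "rates_1x1"), "age label 'young'")
  path3 <- write_lines_tmp(c("t", "", "Year Age Total", "18xx 0 0.1"))
  expect_error(read_hmd_table(path3, "rates_1x1"), "year label")
})

test_that("write-read-assemble round trip is lossless to 1e-9", {
  s <- demo_series()
  dir <- withr::local_tempdir()
  write_hmd_series(s, dir)
  expect_message(
    back <- assemble_vital_series(file.path(dir, "Mx_1x1.txt"),
                                  file.path(dir, "Population.txt"),
                                  file.path(dir, "Births.txt")),
    "assembling")
  expect_identical(back$years, s$years)
  expect_lt(max(abs(back$mortality - s$mortality)), 1e-9)
  expect_lt(max(abs(back$fertility - s$fertility)), 1e-9)
  expect_lt(max(abs(back$migration - s$migration)), 1e-9)
  expect_lt(max(abs(back$population - s$population)) /
              max(s$population), 1e-9)
  expect_lt(max(abs(back$births - s$births)) / max(s$births), 1e-9)
})

test_that("missing years fail loudly instead of being interpolated", {
  s <- constant_series()
  dir <- withr::local_tempdir()
  write_hmd_series(s, dir)
  # drop one year of births inside the span
  bl <- readLines(file.path(dir, "Births.txt"))
  writeLines(bl[!startsWith(bl, "1903")], file.path(dir, "Births.txt"))
  expect_error(
    suppressMessages(assemble_vital_series(file.path(dir, "Mx_1x1.txt"),
                                           file.path(dir, "Population.txt"),
                                           file.path(dir, "Births.txt"))),
    "births for year 1903")
  # a '.' population value inside the span is an error, not a zero
  pl <- readLines(file.path(dir, "Population.txt"))
  i <- grep("^1902\t40", pl)[1]
  pl[i] <- "1902\t40\t.\t.\t."
  writeLines(pl, file.path(dir, "Population.txt"))
  bl2 <- readLines(file.path(dir, "Births.txt"))
  expect_error(
    suppressMessages(suppressWarnings(
      assemble_vital_series(file.path(dir, "Mx_1x1.txt"),
                            file.path(dir, "Population.txt"),
                            file.path(dir, "Births.txt")))),
    "missing values for year 1902")
})

test_that("the decomposition report carries the nine-column layout and its identities", {
  s <- demo_series()
  cf <- project_counterfactuals(s, 1910, 1955, migration = "observed",
                                indices = "prop_65plus")
  d <- decompose_scenarios(cf, "prop_65plus")
  path <- withr::local_tempfile(fileext = ".csv")
  write_decomposition_report(d, path, label = "demo")
  rep_tbl <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(rep_tbl), 1)
  num_cols <- c("initial_value", "final_value", "change_actual",
                "change_both_fixed", "change_fertility_fixed",
                "change_mortality_fixed", "nonvital_pct_of_actual",
                "fertility_pct_of_vital", "mortality_pct_of_vital")
  expect_true(all(num_cols %in% names(rep_tbl)))
  # footnote identities re-derived from the printed (rounded) columns
  expect_equal(rep_tbl$change_actual,
               rep_tbl$final_value - rep_tbl$initial_value, tolerance = 0.11)
  vital <- rep_tbl$change_actual - rep_tbl$change_both_fixed
  fert <- 0.5 * (rep_tbl$change_actual - rep_tbl$change_fertility_fixed +
                   rep_tbl$change_mortality_fixed - rep_tbl$change_both_fixed)
  expect_equal(rep_tbl$fertility_pct_of_vital, 100 * fert / vital, tolerance = 2)
  expect_equal(rep_tbl$fertility_pct_of_vital + rep_tbl$mortality_pct_of_vital,
               100, tolerance = 0.11)
})

test_that("an empty decomposition writes no report", {
  d <- decompose_change(0, 1, 0.5, 0.7, 0.8)[0, ]
  expect_error(write_decomposition_report(d, tempfile()), "empty")
})
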