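#' Read an HMD-style whitespace-delimited table
#'
#' Parses the layout used by long-run single-age demographic databases: a
#' free-text header block, a blank line, a column-header line beginning with
#' `Year`, then whitespace-separated rows. Age labels `"0" .. "109"` parse
#' to integers, the open interval `"110+"` (or any `"<n>+"`) parses to its
#' integer with an open-interval flag, and missing values coded `"."` are
#' kept as `NA` with a file-level warning count — never silently zeroed.
#' Where sex-specific columns are present the both-sexes `Total` column is
#' the one downstream code consumes. Year labels carrying a trailing
#' `+`/`-` (territorial-change duplicates) are collapsed to the later
#' definition.
#'
#' @param path File path.
#' @param layout One of `"rates_1x1"` (Year, Age, ... Total),
#'   `"population_1x1"` (same layout, counts) or `"births_totals"`
#'   (Year, ... Total; no age column).
#' @return An `hmd_table`: a tibble with columns `year`, (`age`, `open`,)
#'   `female`, `male`, `total`, with attributes `layout`, `path` and
#'   `n_missing`.
#' @export
read_hmd_table <- function(path, layout = c("rates_1x1", "population_1x1",
                                            "births_totals")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  hdr <- grep("^\\s*Year\\b", lines)[1L]
  if (is.na(hdr)) abort(sprintf("%s: no column-header line starting with 'Year'.", path))
  header <- strsplit(trimws(lines[hdr]), "\\s+")[[1L]]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) abort(sprintf("%s: no data rows.", path))

  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    abort(sprintf("%s: line %d has %d fields, expected %d.",
                  path, hdr + bad, nf[bad], length(header)))
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- header

  parse_year <- function(x) {
    y <- suppressWarnings(as.integer(sub("[+-]$", "", x)))
    if (anyNA(y)) {
      bad <- which(is.na(y))[1L]
      abort(sprintf("%s: unparseable year label '%s' (line %d).",
                    path, x[bad], hdr + bad))
    }
    y
  }
  num_col <- function(x) {
    x[x == "."] <- NA
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v) & !is.na(x))) {
      bad <- which(is.na(v) & !is.na(x))[1L]
      abort(sprintf("%s: unparseable value '%s' (line %d).", path, x[bad], hdr + bad))
    }
    v
  }

  out <- tibble(year = parse_year(mat[, "Year"]))
  if (layout != "births_totals") {
    if (!"Age" %in% header) abort(sprintf("%s: layout %s needs an Age column.", path, layout))
    age_raw <- mat[, "Age"]
    open <- grepl("^\\d+\\+$", age_raw)
    age <- suppressWarnings(as.integer(sub("\\+$", "", age_raw)))
    if (anyNA(age)) {
      bad <- which(is.na(age))[1L]
      abort(sprintf("%s: unknown age label '%s' (line %d).", path, age_raw[bad], hdr + bad))
    }
    out$age <- age
    out$open <- open
  }
  for (cn in intersect(c("Female", "Male", "Total"), header))
    out[[tolower(cn)]] <- num_col(mat[, cn])
  if (!"total" %in% names(out))
    abort(sprintf("%s: no Total column found.", path))

  # collapse territorial-change duplicates, keeping the later definition
  key <- if ("age" %in% names(out)) paste(out$year, out$age) else as.character(out$year)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    inform(sprintf("%s: %d duplicated year rows collapsed.", path, sum(dup)))
    out <- out[!dup, ]
  }
  n_missing <- sum(is.na(out$total))
  if (n_missing > 0)
    warn(sprintf("%s: %d missing ('.') values retained as NA.", path, n_missing))
  structure(out, layout = layout, path = path, n_missing = n_missing,
            class = c("hmd_table", class(out)))
}

#' Write a simulated series to HMD-style files
#'
#' Emits `Mx_1x1.txt`, `Population.txt` and `Births.txt` in the layout
#' [read_hmd_table()] parses (sex columns carry half the both-sex values).
#' Values are written with 15 significant digits so a write-read-assemble
#' round trip reproduces the series to numerical precision.
#'
#' @param series A [vital_series()] with populations and births.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_hmd_series <- function(series, dir) {
  stopifnot(inherits(series, "vital_series"))
  if (is.null(series$population) || is.null(series$births))
    abort("the series needs populations and births to be written out.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf("%.15g", x)
  age_lab <- c(as.character(series$ages[-length(series$ages)]),
               paste0(series$a_max, "+"))

  write_block <- function(file, title, header, rows) {
    readr::write_lines(c(title, "", header, rows), file)
    file
  }
  p1 <- file.path(dir, "Mx_1x1.txt")
  rows <- unlist(lapply(seq_along(series$years), function(j) {
    v <- series$mortality[, j]
    sprintf("%d\t%s\t%s\t%s\t%s", series$years[j], age_lab,
            fmt(v / 2), fmt(v / 2), fmt(v))
  }))
  write_block(p1, "Simulated series, Death rates (period 1x1)",
              "Year\tAge\tFemale\tMale\tTotal", rows)

  p2 <- file.path(dir, "Population.txt")
  rows <- unlist(lapply(seq_along(series$pop_years), function(j) {
    v <- series$population[, j]
    sprintf("%d\t%s\t%s\t%s\t%s", series$pop_years[j], age_lab,
            fmt(v / 2), fmt(v / 2), fmt(v))
  }))
  write_block(p2, "Simulated series, Population size (1-Jan, 1x1)",
              "Year\tAge\tFemale\tMale\tTotal", rows)

  p3 <- file.path(dir, "Births.txt")
  rows <- sprintf("%d\t%s\t%s\t%s", series$years,
                  fmt(series$births / 2), fmt(series$births / 2),
                  fmt(series$births))
  write_block(p3, "Simulated series, Births", "Year\tFemale\tMale\tTotal", rows)
  invisible(c(p1, p2, p3))
}

#' Assemble a vital series from HMD-style tables
#'
#' Builds the projection inputs the way long-run analyses must: mortality
#' straight from the rates table, age-specific fertility by indirect
#' standardisation of annual births ([estimate_fertility_indirect()]), and
#' net migration residually by the balancing equation
#' ([estimate_net_migration()], with birth-cohort deaths defaulted to the
#' engine's newborn half-year exposure). The series is truncated to the
#' longest contiguous span over which rates, births, and populations at
#' both year ends are all available; missing values inside that span raise
#' an error naming the year — gaps are never interpolated.
#'
#' @param mx,population,births `hmd_table` objects from [read_hmd_table()]
#'   (or file paths, which are read with the matching layout).
#' @param standard Standard fertility shape for the indirect
#'   standardisation (default [standard_fertility()]).
#' @return A [vital_series()] with estimated fertility and migration,
#'   observed mortality, births and populations.
#' @export
assemble_vital_series <- function(mx, population, births, standard = NULL) {
  if (is.character(mx)) mx <- read_hmd_table(mx, "rates_1x1")
  if (is.character(population)) population <- read_hmd_table(population, "population_1x1")
  if (is.character(births)) births <- read_hmd_table(births, "births_totals")

  yrs_rates <- sort(unique(mx$year))
  yrs_pop <- sort(unique(population$year))
  common <- intersect(yrs_rates, yrs_pop[(yrs_pop + 1L) %in% yrs_pop])
  if (!length(common)) abort("no common year span across rates and populations.")
  common <- sort(common)
  runs <- split(common, cumsum(c(1L, diff(common) != 1L)))
  years <- runs[[which.max(lengths(runs))]]
  if (length(years) < 2) abort("the common span is shorter than two years.")
  inform(sprintf("assembling series over %d-%d.", min(years), max(years)))

  ages <- sort(unique(mx$age))
  a_max <- max(ages)
  if (!identical(as.integer(ages), 0:a_max))
    abort("the rates table must cover every single age 0..a_max.")

  grab <- function(tb, col, yrs) {
    m <- matrix(NA_real_, a_max + 1L, length(yrs), dimnames = list(0:a_max, yrs))
    sel <- tb$year %in% yrs
    m[cbind(tb$age[sel] + 1L, match(tb$year[sel], yrs))] <- tb[[col]][sel]
    if (anyNA(m)) {
      j <- which(colSums(is.na(m)) > 0)[1L]
      abort(sprintf("missing values for year %s; gaps are not interpolated.", yrs[j]))
    }
    m
  }
  mort <- grab(mx, "total", years)
  popm <- grab(population, "total", c(years, max(years) + 1L))
  b <- setNames(births$total, births$year)[as.character(years)]
  if (anyNA(b))
    abort(sprintf("missing births for year %s.", years[which(is.na(b))[1L]]))

  std <- standard %||% standard_fertility(0:a_max)
  pop_tbl <- as_pop_tbl(popm)
  fert_tbl <- estimate_fertility_indirect(
    pop_tbl[pop_tbl$year %in% years, ],
    tibble(year = years, births = unname(b)), std)
  fert <- matrix(0, a_max + 1L, length(years), dimnames = list(0:a_max, years))
  fert[cbind(fert_tbl$age + 1L, match(fert_tbl$year, years))] <- fert_tbl$fertility

  # cohort deaths implied by the rate schedules (engine convention)
  q <- rate_to_probability(mort)
  deaths <- popm[, seq_along(years), drop = FALSE] * q
  nb_deaths <- 0.5 * q[1L, ] * b
  deaths_tbl <- bind_rows(
    as_pop_tbl(deaths) |> rename(deaths = "count"),
    tibble(year = years, age = -1L, deaths = unname(nb_deaths)))
  mig_tbl <- estimate_net_migration(pop_tbl,
                                    deaths_tbl,
                                    tibble(year = years, births = unname(b)))
  mig <- matrix(0, a_max + 1L, length(years), dimnames = list(0:a_max, years))
  sel <- mig_tbl$age >= 0
  mig[cbind(mig_tbl$age[sel] + 1L, match(mig_tbl$year[sel], years))] <-
    ifelse(is.na(mig_tbl$rate[sel]), 0, mig_tbl$rate[sel])
  nb_mig <- setNames(rep(0, length(years)), years)
  nbm <- mig_tbl[mig_tbl$age == -1L, ]
  nb_mig[as.character(nbm$year)] <- ifelse(is.na(nbm$rate), 0, nbm$rate)

  new_vital_series(
    years = years, fertility = fert, mortality = mort, migration = mig,
    newborn_migration = nb_mig, births = b,
    deaths = deaths, newborn_deaths = nb_deaths,
    population = popm, pop_years = c(years, max(years) + 1L)
  )
}

#' Write a summary-table-shaped decomposition report
#'
#' Emits a CSV with the nine numbered columns of the standard all-country
#' summary layout — initial and final index values, the four scenario
#' changes, the non-vital share of actual change, and the fertility and
#' mortality shares of the vital component — plus metadata columns
#' (`label`, `index`, `base_year`, `final_year`). Column formulas: col 3 =
#' col 2 - col 1; col 7 = 100 * col 4 / col 3; col 8 = 100 * fertility
#' component / vital component; col 9 = 100 * mortality component / vital
#' component. Values are rounded to one decimal (round-half-even).
#'
#' @param decomp An `ageing_decomposition` tibble (rows may be bound from
#'   several countries/runs); must carry `base_value` levels, as produced
#'   by [decompose_scenarios()].
#' @param path Output CSV path.
#' @param label Optional character vector of row labels.
#' @return Invisibly, the report tibble that was written.
#' @export
write_decomposition_report <- function(decomp, path, label = NULL) {
  stopifnot(inherits(decomp, "ageing_decomposition"))
  if (!nrow(decomp)) abort("empty decomposition; no report written.")
  r1 <- function(x) round(x, 1)
  rep_tbl <- tibble(
    label = label %||% paste0("row", seq_len(nrow(decomp))),
    index = decomp$index,
    base_year = decomp$base_year, final_year = decomp$final_year,
    initial_value = r1(decomp$base_value),
    final_value = r1(decomp$base_value + decomp$actual_change),
    change_actual = r1(decomp$actual_change),
    change_both_fixed = r1(decomp$change_bf),
    change_fertility_fixed = r1(decomp$change_ff),
    change_mortality_fixed = r1(decomp$change_mf),
    nonvital_pct_of_actual = r1(decomp$nonvital_pct_of_actual),
    fertility_pct_of_vital = r1(decomp$fertility_pct_of_vital),
    mortality_pct_of_vital = r1(decomp$mortality_pct_of_vital)
  )
  readr::write_csv(rep_tbl, path)
  invisible(rep_tbl)
}
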