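#' Indicators of population ageing
#'
#' Alternative scalar summaries of an age structure, each computed from a
#' tidy population data frame with columns `age` and `count` (and optionally
#' `year`, see [ageing_indices()]):
#'
#' * `prop_65plus()` — percentage of the population aged 65 and over;
#' * `mean_age()` — mean age in years, using the midpoint convention
#'   `a + 0.5` for counts in completed-age interval `a` (the open top
#'   interval contributes `a_max + 0.5`);
#' * `median_age()` — median age, linearly interpolated within the
#'   single-year interval in which the cumulative share reaches one half;
#' * `oadr()` — old-age dependency ratio, persons 65+ per person 15-64.
#'
#' All indices are invariant to rescaling the counts.
#'
#' @param pop Data frame with columns `age` (integer) and `count`
#'   (non-negative), one row per age; total count must be positive.
#' @param age_min For `prop_65plus()`, the lower bound of "old" (default 65).
#' @param old,working For `oadr()`, the old-age lower bound and the working
#'   age range (defaults 65 and 15-64).
#' @return A single numeric value: per cent for `prop_65plus()`, years for
#'   `mean_age()` and `median_age()`, a ratio for `oadr()`.
#' @examples
#' uni <- data.frame(age = 0:99, count = rep(1, 100))
#' prop_65plus(uni)  # 35
#' mean_age(uni)     # 50
#' oadr(uni)         # 0.7
#' @name ageing-index
NULL

check_pop <- function(pop) {
  stopifnot(is.data.frame(pop), all(c("age", "count") %in% names(pop)))
  if (any(pop$count < 0)) abort("population counts must be non-negative.")
  if (sum(pop$count) <= 0) abort("the population is empty; indices are undefined.")
  pop[order(pop$age), , drop = FALSE]
}

#' @rdname ageing-index
#' @export
prop_65plus <- function(pop, age_min = 65) {
  pop <- check_pop(pop)
  100 * sum(pop$count[pop$age >= age_min]) / sum(pop$count)
}

#' @rdname ageing-index
#' @export
mean_age <- function(pop) {
  pop <- check_pop(pop)
  sum((pop$age + 0.5) * pop$count) / sum(pop$count)
}

#' @rdname ageing-index
#' @export
median_age <- function(pop) {
  pop <- check_pop(pop)
  cum <- cumsum(pop$count)
  half <- 0.5 * sum(pop$count)
  i <- which(cum >= half)[1L]
  below <- if (i == 1L) 0 else cum[i - 1L]
  pop$age[i] + (half - below) / pop$count[i]
}

#' @rdname ageing-index
#' @export
oadr <- function(pop, old = 65, working = c(15, 64)) {
  pop <- check_pop(pop)
  denom <- sum(pop$count[pop$age >= working[1] & pop$age <= working[2]])
  if (denom <= 0) abort("no population in the working ages; dependency ratio undefined.")
  sum(pop$count[pop$age >= old]) / denom
}

index_funs <- list(
  prop_65plus = prop_65plus,
  mean_age = mean_age,
  median_age = median_age,
  oadr = oadr
)

#' Evaluate ageing indices, optionally along a trajectory
#'
#' Applies any subset of the ageing indices to a population data frame. When
#' `pop` carries a `year` column the indices are evaluated separately for
#' every year, yielding the index series \eqn{a^x(t)} of a projection.
#'
#' @param pop Data frame with columns `age`, `count` and optionally `year`.
#' @param indices Character vector naming the indices; any of
#'   `"prop_65plus"`, `"mean_age"`, `"median_age"`, `"oadr"`. These names are
#'   the stable identifiers used across results, reports and the CLI.
#' @return Tibble with columns (`year`,) `index`, `value`.
#' @export
ageing_indices <- function(pop, indices = c("prop_65plus", "mean_age",
                                            "median_age", "oadr")) {
  bad <- setdiff(indices, names(index_funs))
  if (length(bad))
    abort(sprintf("unknown index name(s): %s", paste(bad, collapse = ", ")))
  one <- function(df) {
    tibble(index = indices,
           value = purrr::map_dbl(indices, ~ index_funs[[.x]](df)))
  }
  if ("year" %in% names(pop)) {
    pop |> group_by(.data$year) |> group_modify(~ one(.x)) |> ungroup()
  } else {
    one(pop)
  }
}
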