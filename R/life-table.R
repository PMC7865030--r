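#' Convert central death rates to conditional death probabilities
#'
#' Converts an age-specific central death rate \eqn{m} (deaths per
#' person-year) into the probability \eqn{q} of dying within the one-year age
#' interval, assuming a constant hazard within the interval:
#' \eqn{q = 1 - e^{-m}}. This form is bounded in \eqn{[0, 1)} for any finite
#' rate, unlike the Greville approximation \eqn{m/(1 + 0.5m)}, and at
#' single-year intervals the two differ negligibly.
#'
#' @param m Numeric vector of central death rates, all `>= 0`.
#' @return Numeric vector of death probabilities, same length as `m`.
#' @seealso [probability_to_rate()] for the exact inverse.
#' @examples
#' rate_to_probability(c(0, 0.1, 1))
#' @export
rate_to_probability <- function(m) {
  if (!is.numeric(m) || anyNA(m)) abort("`m` must be numeric with no missing values.")
  if (any(m < 0)) abort("central death rates must be non-negative.")
  -expm1(-m)
}

#' Convert conditional death probabilities back to central rates
#'
#' Exact inverse of [rate_to_probability()]: \eqn{m = -\log(1 - q)}.
#'
#' @param q Numeric vector of death probabilities in `[0, 1)`.
#' @return Numeric vector of central death rates.
#' @export
probability_to_rate <- function(q) {
  if (!is.numeric(q) || anyNA(q)) abort("`q` must be numeric with no missing values.")
  if (any(q < 0) || any(q >= 1)) abort("death probabilities must lie in [0, 1).")
  -log1p(-q)
}

#' Build a single-decrement period life table
#'
#' Constructs a life table from a schedule of central death rates on single
#' years of age `0 .. A` with an open-ended top interval ("A and over").
#' Probabilities come from [rate_to_probability()] except at the top age,
#' where `qx = 1` (everyone reaching the open interval eventually dies in
#' it). Survivorship uses a radix of 1, and person-years use the midpoint
#' separation factor at every closed age:
#' `Lx = lx * (1 - 0.5 * qx)`, with the open interval closed out by
#' `Lx = lx / mx`.
#'
#' @param mx Numeric vector of central death rates for ages `0 .. A` (the
#'   last element is the open interval). The top-age rate must be positive,
#'   otherwise the open interval cannot be closed.
#' @param ages Optional integer vector of age labels; defaults to
#'   `0:(length(mx) - 1)`.
#' @return A tibble with columns `age`, `mx`, `qx`, `lx`, `Lx`.
#' @examples
#' lt <- life_table(c(0.01, 0.002, 0.5))
#' life_expectancy(lt)
#' @export
life_table <- function(mx, ages = NULL) {
  if (is.data.frame(mx)) {
    df <- mx
    if (!all(c("age", "mortality") %in% names(df)))
      abort("a data-frame `mx` needs columns `age` and `mortality`.")
    ages <- df$age
    mx <- df$mortality
  }
  if (!is.numeric(mx) || length(mx) < 2 || anyNA(mx))
    abort("`mx` must be a numeric vector (length >= 2) with no missing values.")
  if (any(mx < 0) || any(!is.finite(mx))) abort("central death rates must be finite and non-negative.")
  mx <- unname(mx)
  n <- length(mx)
  if (mx[n] <= 0) abort("the open-interval rate mx[A] must be positive to close the life table.")
  ages <- ages %||% (0:(n - 1L))
  qx <- rate_to_probability(mx)
  qx[n] <- 1
  lx <- cumprod(c(1, 1 - qx[-n]))
  Lx <- lx * (1 - 0.5 * qx)
  Lx[n] <- lx[n] / mx[n]
  tibble(age = as.integer(ages), mx = mx, qx = qx, lx = lx, Lx = Lx)
}

#' Period life expectancy at birth from a life table
#'
#' @param lt A life table as returned by [life_table()].
#' @return Life expectancy at birth in years (`sum(Lx)` with radix 1).
#' @export
life_expectancy <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("lx", "Lx") %in% names(lt)))
  sum(lt$Lx)
}
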