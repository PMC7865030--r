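#' Intrinsic (Lotka) growth rate of a fertility-mortality regime
#'
#' Solves the discrete Euler-Lotka renewal equation for the unique real
#' growth rate `r` implied by fixed fertility and mortality with zero
#' migration. Two discretisations are available:
#'
#' * `method = "projection"` (default): the characteristic equation of the
#'   package's own projection step,
#'   \deqn{(1 - 0.5 q_0) \sum_a f(a) e^{-r(a+1)} l(a) = 1,}
#'   whose root is, to machine precision, the asymptotic growth rate of a
#'   fixed-rate zero-migration projection run with [project_scenario()].
#'   Use this whenever stable-population quantities are compared with
#'   projection output.
#' * `method = "midpoint"`: the textbook midpoint form
#'   \deqn{\sum_a f(a) e^{-r(a+0.5)} L(a) = 1,}
#'   consistent with the `a + 0.5` mean-age convention. It differs from the
#'   projection form by terms of order of the within-interval survival
#'   approximation.
#'
#' The root is found by bracketed bisection starting from `interval`
#' (per-year growth rates of \eqn{\pm 0.2} cover any human population) and
#' expanding geometrically if needed, to a tolerance of 1e-12.
#'
#' @param fertility Numeric fertility schedule on the life-table ages
#'   (both-sexes convention), or a data frame with `age` and `fertility`.
#' @param lt Life table from [life_table()] built from the matching
#'   mortality schedule.
#' @param method `"projection"` or `"midpoint"`.
#' @param interval Initial root bracket (per-year growth rate).
#' @return The intrinsic growth rate per year (a single number).
#' @export
lotka_r <- function(fertility, lt, method = c("projection", "midpoint"),
                    interval = c(-0.2, 0.2)) {
  method <- match.arg(method)
  if (is.data.frame(fertility)) fertility <- fertility$fertility[order(fertility$age)]
  stopifnot(is.data.frame(lt), nrow(lt) == length(fertility))
  if (sum(fertility * lt$Lx) <= 0)
    abort("net reproduction is zero; no real Lotka root exists.")
  g <- lotka_residual_fun(fertility, lt, method)
  lo <- interval[1]; hi <- interval[2]
  for (k in 1:60) {
    if (g(lo) > 0 && g(hi) < 0) break  # g is decreasing in r
    lo <- lo * 2; hi <- hi * 2
    if (k == 60) abort("failed to bracket the Lotka root.")
  }
  uniroot(g, c(lo, hi), tol = 1e-14)$root
}

# residual g(r) = (Lotka sum) - 1, strictly decreasing in r
lotka_residual_fun <- function(fertility, lt, method) {
  age <- lt$age
  if (method == "projection") {
    s0 <- 1 - 0.5 * lt$qx[1L]
    function(r) s0 * sum(fertility * exp(-r * (age + 1)) * lt$lx) - 1
  } else {
    function(r) sum(fertility * exp(-r * (age + 0.5)) * lt$Lx) - 1
  }
}

#' Stable age distribution implied by a growth rate and life table
#'
#' The age-share vector of the stable population. With
#' `method = "projection"` the shares reproduce the exact fixed point of the
#' projection step: `c(a)` proportional to `exp(-r a) l(a)` at closed ages,
#' with the open top interval accumulating geometrically,
#' `c(A) = c(A-1) p(A-1) / (e^r - p(A))` where `p` are one-year survival
#' probabilities and `p(A) = exp(-m(A))`. With `method = "midpoint"`,
#' `c(a)` is proportional to `exp(-r (a + 0.5)) L(a)` at every age.
#'
#' @param r Intrinsic growth rate per year (from [lotka_r()]).
#' @param lt Life table from [life_table()].
#' @param method `"projection"` or `"midpoint"` (match the method used for
#'   `r`).
#' @return Tibble with columns `age`, `share` (`sum(share) == 1`).
#' @export
stable_age_distribution <- function(r, lt, method = c("projection", "midpoint")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(lt), all(c("age", "lx", "Lx", "qx", "mx") %in% names(lt)))
  n <- nrow(lt)
  if (method == "projection") {
    lam <- exp(r)
    u <- lam^(-lt$age) * lt$lx
    p_top <- exp(-lt$mx[n])
    if (lam <= p_top)
      abort("the open interval does not converge: growth rate below top-age survival.")
    u[n] <- u[n - 1L] * (1 - lt$qx[n - 1L]) / (lam - p_top)
  } else {
    u <- exp(-r * (lt$age + 0.5)) * lt$Lx
  }
  tibble(age = lt$age, share = u / sum(u))
}

#' Stable-population solution for a fixed-rate regime
#'
#' Convenience wrapper returning the intrinsic growth rate, stable age
#' distribution and the ageing-index values of the stable population — the
#' non-ageing limit a fixed-rate, zero-migration projection converges to.
#'
#' @inheritParams lotka_r
#' @param indices Ageing index names to evaluate on the stable structure.
#' @return List of class `stable_solution` with elements `r`, `distribution`
#'   (tibble `age`, `share`) and `index_values` (tibble `index`, `value`).
#' @export
stable_solution <- function(fertility, lt, method = c("projection", "midpoint"),
                            indices = c("prop_65plus", "mean_age",
                                        "median_age", "oadr")) {
  method <- match.arg(method)
  r <- lotka_r(fertility, lt, method)
  dist <- stable_age_distribution(r, lt, method)
  idx <- ageing_indices(tibble(age = dist$age, count = dist$share), indices)
  structure(list(r = r, distribution = dist, index_values = idx,
                 method = method),
            class = "stable_solution")
}

#' @export
print.stable_solution <- function(x, ...) {
  cat(sprintf("<stable_solution> r = %.6f per year (%s discretisation)\n",
              x$r, x$method))
  for (i in seq_len(nrow(x$index_values)))
    cat(sprintf("  %-12s %10.4f\n", x$index_values$index[i], x$index_values$value[i]))
  invisible(x)
}

#' Relaxation time of an ageing index under fixed rates
#'
#' Years until an index series from a fixed-rate projection becomes
#' effectively constant: the smallest `t >= 1` (years since the base year)
#' such that every subsequent year-on-year change is below `epsilon` within
#' the projected horizon. Indicators weighted towards old ages (such as the
#' proportion 65+) are driven by events up to a lifetime earlier and
#' typically relax more slowly than whole-distribution indicators such as
#' the mean age.
#'
#' @param x A `scenario_projection` (a fixed-rate `Bf`-type run).
#' @param index Index name present in the run.
#' @param epsilon Convergence tolerance on the year-on-year change, in the
#'   index's own units.
#' @return Tibble with columns `index`, `epsilon`, `years`, `converged`
#'   (`years` is `NA` when the tolerance is never met within the horizon).
#' @export
relaxation_time <- function(x, index, epsilon) {
  stopifnot(inherits(x, "scenario_projection"))
  v <- x$index_series |> filter(.data$index == !!index) |> arrange(.data$year)
  if (!nrow(v)) abort(sprintf("index '%s' was not evaluated in this run.", index))
  d <- abs(diff(v$value))
  ok <- rev(cumall_true(rev(d < epsilon)))
  t_rel <- which(ok)[1L]
  tibble(index = index, epsilon = epsilon,
         years = if (is.na(t_rel)) NA_integer_ else as.integer(t_rel),
         converged = !is.na(t_rel))
}

cumall_true <- function(x) cumprod(x) > 0
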