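---
title: "Counterfactual projections and the decomposition of population ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual projections and the decomposition of population ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agedecomp)
library(dplyr)
```

## The question the package answers

Populations age because of three forces: fertility decline (fewer young
people entering at the bottom of the pyramid), mortality improvement
(survivors accumulating at the top), and the momentum stored in the initial
age structure, modulated by migration. A long-standing way to apportion
ageing between fertility and mortality is the *counterfactual projection*:
re-run history with one vital rate frozen at its base-year schedule and
compare the outcome with what actually happened. `agedecomp` implements
this machinery end to end — the projection engine, the scenario set, an
exactly additive decomposition, the stable-population theory that anchors
it, the rate estimators needed to build inputs from standard single-age
data files, and a seeded simulator so that every claim is testable without
any external download.

## The projection model

The engine is a standard one-year cohort-component model on single years of
age $0,\dots,A$ with an open top interval ($A$ = 110 by default, the layout
of long-run mortality databases). Writing $N(a,t)$ for the start-of-year
population, $m(a,t)$ for central death rates, $f(a,t)$ for both-sex
fertility rates and $M(a,t)$ for net migration rates:

* death probabilities use the constant-hazard form $q = 1 - e^{-m}$, which
  is bounded in $[0,1)$ for any finite rate; at single-year intervals it is
  numerically indistinguishable from the classical $m/(1+m/2)$;
* survivors move up one age, $N(a{+}1,t{+}1) = N(a,t)(1-q(a,t))$, and the
  open interval accumulates, with its survival taken from the open-interval
  rate itself rather than the life-table convention $q(A)=1$;
* births $B(t) = \sum_a f(a,t) N(a,t)$ are exposed to half a year of infant
  mortality: $N(0,t{+}1) = B(t)(1 - \tfrac12 q(0,t))$;
* net migrants $M(a,t)N(a,t)$ are added after survival at the cohort's
  destination age and are exempt from mortality in the year of arrival; the
  in-year birth cohort has its own rate with base $B(t)$.

The migration timing convention is declared, not inferred: nothing in the
method constrains it, and this choice makes the balancing-equation
estimator (`estimate_net_migration()`) the *exact* inverse of the engine's
migration step, which the tests exploit as a machine-precision round trip.
Counts driven negative by large estimated out-migration rates at sparse
ages are clipped to zero with a warning.

Four scenarios share one initial population: `Ac` (actual fertility and
mortality), `Bf` (both frozen at the base-year schedules), `Mf` (mortality
frozen) and `Ff` (fertility frozen). Migration is handled orthogonally as
`zero`, `observed`, or `fixed` — fixed *rates*, not fixed counts, because
scenario population sizes diverge by an order of magnitude over a century
and a fixed count has no coherent meaning across them.

## The decomposition

For any ageing index $a^x(t)$ evaluated on scenario $x$, the change between
the base year and a later year splits as

$$\underbrace{a^{Ac}(T) - a^{Bf}(T)}_{\text{vital}} +
  \underbrace{a^{Bf}(T) - a^{Ac}(0)}_{\text{non-vital}},$$

and the vital part splits further into a mortality component
$\tfrac12\!\left(a^{Ac} - a^{Mf} + a^{Ff} - a^{Bf}\right)$ and a fertility
component $\tfrac12\!\left(a^{Ac} - a^{Ff} + a^{Mf} - a^{Bf}\right)$ —
each the average of the two available fixed-versus-actual contrasts. The
averaging makes the two components sum *exactly* to the vital component,
and vital + non-vital is exactly the observed change; both identities hold
to machine precision by construction and are asserted over thousands of
random inputs in the test suite. When the vital component is within
`1e-9` of zero the percentage shares are reported as undefined rather than
blowing up.

The non-vital component is the part older comparisons silently
misattribute: contrasting $a^{Mf}(T)$ or $a^{Ff}(T)$ directly with the
baseline value folds the momentum of the initial age structure into
"fertility" or "mortality". `naive_comparison()` returns those legacy
contrasts next to the corrected components; they agree only when the
initial structure is already the stable population of the base-year rates.

Two structural caveats are built into the API rather than hidden. First,
the decomposition is not transitive: components over adjoining
sub-intervals need not sum to the whole-interval components, and a test
demonstrates the inequality on a designed series. Second, results are
sensitive to the base year — freezing fertility just before or just after
a sharp fertility drop flips which driver dominates, which the test suite
reproduces synthetically. `decompose_windowed()` separates *influence
time* (the projection launched at the base year) from *analysis time* (a
short window, e.g. 1 or 5 years, at the end), averaging component values
over all (base, final) pairs with equal weight and recomputing shares from
the averaged components.

Report columns follow the conventional nine-column summary layout; the
share columns are computed as 100 × component / vital component as defined
above (the writer documents its own formulas in its help page).

## Stable-population anchor

Under frozen rates and zero migration the projection converges to a stable
population that grows at a constant rate and stops ageing. The package
solves for that limit directly. A deliberate design choice: the default
discretisation of the Euler–Lotka equation is the *characteristic equation
of the projection step itself*,

$$(1 - \tfrac12 q_0)\sum_a f(a)\, e^{-r(a+1)}\, l(a) = 1,$$

with the stable shares $c(a) \propto e^{-ra} l(a)$ and a geometric open
interval $c(A) = c(A{-}1)p(A{-}1)/(e^r - p(A))$. With this form the
long-run growth rate and age distribution of a `Bf` run match `lotka_r()`
and `stable_age_distribution()` to machine precision — internal
consistency between the dynamic and static views is worth more than
fidelity to any single textbook variant. The textbook midpoint form
$\sum_a f(a) e^{-r(a+0.5)} L(a) = 1$ is available as `method = "midpoint"`;
it differs from the projection form by within-interval survival terms,
i.e. in the third or fourth decimal of $r$ for human-like schedules, which
is far larger than the `1e-12` root-finding tolerance, so the two methods
must not be mixed within one analysis.

Relaxation times (`relaxation_time()`) quantify how long an index takes to
become effectively constant under fixed rates. Indices weighted towards
old ages — the proportion 65+ — are driven by events up to a lifetime
earlier and relax more slowly than the mean age; a test asserts the
ordering.

On convergence speed: the ratio of the subdominant to the dominant
eigenvalue of the one-year projection (Leslie) matrix is about 0.97 per
year for realistic single-age fertility schedules. Two maximally different
*viable* starting structures — everyone at age 0 versus everyone at the top
of the reproductive span — therefore differ in age-distribution sup-norm
by roughly $2\times10^{-6}$ after 300 years, crossing $10^{-6}$ around
years 330–350. A structure lying wholly above the reproductive span can
never converge at all: it produces no births, so "all mass old" is taken
to mean the oldest age from which the population remains viable.

## Rate estimation from standard data files

Long-run single-age data collections provide death rates, populations and
total births, but not age-specific fertility, and migration only
implicitly. The package builds the missing inputs the standard way:

* **Indirect standardisation** (`estimate_fertility_indirect()`): a fixed
  standard age shape $s(a)$ is scaled by $k(t) = B(t)/\sum_a s(a)N(a,t)$
  so fitted rates reproduce observed births exactly. The default shape is
  a smooth Beta curve on ages 15–49 peaking near 28 — a conventional
  schedule, since only the level, not the shape, is identified by annual
  birth totals. Attributions to fertility can shift slightly under a
  different shape; per-year shapes may be supplied.
* **Balancing equation** (`estimate_net_migration()`): net migration as
  the cohort residual $N(a{+}1,t{+}1) - N(a,t) + D(a,t)$, divided by the
  start-of-year stock. The two cohorts entering the open interval cannot
  be separated, so their pooled rate is reported for both top ages.
  Missing birth-cohort deaths default to $\tfrac12 q(0)B(t)$, the engine's
  own newborn exposure.

`read_hmd_table()` parses the whitespace-delimited dialect (header block,
`Year`/`Age` columns, `110+` open age, `.` missing markers kept as flagged
`NA`s — never zeroed), and `assemble_vital_series()` wires everything into
a projection-ready series, refusing to interpolate missing years: silent
gap-filling would corrupt a decomposition unnoticed.

## The simulator and what passing tests do (and do not) show

`sim_transition_series()` generates the study conditions: a demographic
transition on ages 0–110+ over a configurable span (default 1850–2015),
with a logistic TFR decline (default 4.5 to 1.8 centred on 1930, time
scale 8 years — an optional step path reproduces a sharp inter-war-style
drop), Gompertz–Makeham mortality whose overall scale is tuned by a
monotone scalar search (tolerance 0.01 years) to a logistic
life-expectancy path (default 40 to 80 years centred on 1920), optional
Gaussian-profile migration waves peaking at age 25, and multiplicative
log-normal rate noise under per-component seed streams (off by default).
The labelled start year follows a 150-year fixed-rate burn-in from the
initial rates' own stable structure, so an 1850-style start is a settled
pre-transition population whose fixed-rate projection is flat.
Life-expectancy targets outside 10–100 years are refused by name of the
offending year: below that range the Gompertz shape cannot bend enough,
above it the "solution" would live in the open interval's tail.

Because the simulator's populations are produced by the engine itself, the
estimator round trips and scenario self-consistency checks are exact by
construction; they validate the *bookkeeping*, not the realism of any
particular country. What the synthetic tests cannot show: real series
carry cohort/period rate splices, wars, pandemics, territorial changes and
genuinely age-structured fertility change, none of which the generator
emulates. Conclusions about any real population require real inputs
through `assemble_vital_series()`.

Problem sizes used by the tests and the acceptance script — chosen as the
smallest that exercise every regime: series of 4–90 years for unit checks,
a 61-year transition with a migration wave for estimator round trips,
and 300–400-year fixed-rate runs for the stable-population diagnostics.

## Numerical conventions and edge cases

* Ageing indices use the midpoint convention: counts in completed-age
  interval $a$ contribute $a + 0.5$ to the mean age, the open interval
  contributes $A + 0.5$, and the median interpolates linearly within its
  single-year interval. All indices are scale invariant and monotone under
  a one-age upward shift of all mass.
* The old-age dependency ratio uses 65+ over 15–64; both bounds are
  arguments.
* Percentage shares in reports are rounded to one decimal with R's
  round-half-even; published tables rounded from unrounded inputs can
  therefore differ by ±0.1, and reproduction from printed columns is
  asserted at ±0.2.
* Lotka root finding brackets $[-0.2, 0.2]$ per year (all human
  populations) and expands geometrically if a pathological schedule needs
  it; zero net reproduction is an error, not a root.
* A projection horizon beyond the observed series is allowed only when
  every year-varying input is frozen (`Bf`-type diagnostics); "actual"
  scenarios refuse it.

## A worked example

```{r example, eval = FALSE}
tab <- european_ageing_1900()
d <- decompose_change(0, ac = tab$change_actual, bf = tab$change_both_fixed,
                      mf = tab$change_mortality_fixed,
                      ff = tab$change_fertility_fixed,
                      index = "prop_65plus")
glance(d)

# a fully synthetic pipeline: simulate, project, decompose
s <- sim_transition_series(years = 1900:1990, seed = 1)
cf <- project_counterfactuals(s, base_year = 1920, final_year = 1990,
                              migration = "zero", indices = "prop_65plus")
decompose_scenarios(cf, "prop_65plus")
autoplot(cf)
```

## Known limitations

Single-sex (both-sexes-combined) projection only; no stochastic or
multiregional variants; no tempo adjustment of period fertility, whose
sensitivity to timing shifts is one reason base-year choice matters so
much; stable populations are defined without migration, as the competing
migration-inclusive specifications in the literature are mutually
inconsistent; and the decomposition inherits the method's own documented
weaknesses — base-year sensitivity and non-transitivity — which the
package demonstrates rather than hides.
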