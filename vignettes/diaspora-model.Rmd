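---
title: "The diaspora model: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diaspora model: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diasporaflow)
```

## The model

`diasporaflow` implements a two-stage hierarchical model of international
migration into a single destination country observed over a window of `t`
days. The only covariate is the diaspora stock matrix `R`, where `R[i, j]`
counts people from origin `i` already resident in destination `j` (a postal
code, district, metro area — any partition of the country) at the start of
the window.

1. **Intensity.** Arrivals from origin `i` form a homogeneous Poisson
   process: `M_i(t) ~ Pois(λ_i t)` with `λ_i = ρ R_i`, `R_i = Σ_j R[i, j]`.
   The *pull rate* ρ (arrivals per diaspora member per day) is shared by all
   origins: a community of 10,000 with ρ = 3.29e-4 attracts about 3.3 new
   arrivals per day.
2. **Assortativity.** Conditional on `M_i(t) = m`, destinations are chosen
   multinomially with probabilities `π_ij = R_ij / R_i` — migrants settle
   where their compatriots already live, in proportion to the local diaspora
   share.

Poisson thinning makes the cell counts independent Poissons,
`M_ij(t) ~ Pois(ρ R_ij t)`, which has two consequences the package leans on:
expected flows `ρ R_ij t` are linear in the stocks and therefore aggregate
exactly over any destination partition (`aggregate_destinations()`), and
hierarchical simulation (totals, then allocation) is distributionally
identical to direct per-cell sampling — a property the test suite checks by
moments and a chi-square goodness-of-fit.

**Assumptions.** The rate is constant over the window (no seasonality, no
shocks, weekend dips averaged out); stocks are frozen (no births, deaths or
departures during the window); origins are independent; and a diaspora must
exist for the model to speak — `assortativity_probs()` and the estimators
raise an error for an origin with `R_i = 0` rather than inventing a
distribution, since the mechanism being modelled (information flow and
lowered settlement costs through an existing community) is absent there.

## Estimators

Both estimators are closed-form least-squares solutions, and both are tested
against brute-force minimization of their objective functions.

- `estimate_lambda()` minimises `Σ_{t=0}^{n} (M(t) − λt)²` over the daily
  cumulative series of one origin, giving
  `λ* = 6 Σ_t t·M(t) / (n(n+1)(2n+1))`. The sum includes `t = 0`
  (contributing nothing) and the series is window-relative with `M(0) = 0`.
  On a noiseless linear series the estimator returns the slope exactly.
- `estimate_pull_rate()` minimises `Σ_i (M_i − ρ R_i t)²` across origins,
  giving `ρ* = Σ_i M_i R_i / (t Σ_i R_i²)`. This is the minimiser implied by
  the objective's second derivative `2 Σ_i R_i² t² > 0`; note the factor `t`
  sits in the denominator, not the numerator.

Least squares rather than maximum likelihood keeps the estimators closed-form
and dependency-free; at the regimes of interest (`λt` in the hundreds or
more) the difference from the Poisson MLE is negligible, and the parameter
recovery study below quantifies the achieved accuracy directly.

## Bands, the constant-rate check, and forecasting

For a Poisson expectation `λt`, `normal_band()` returns
`λt ± θ√(λt)`. Two multipliers are defaults in different roles:

- `θ = 4` for `constant_rate_check()`. The check re-estimates `λ*` from the
  series and asks whether `M(t)` stays inside the envelope for every day
  `t ≥ t_min` (default: the first day with `λ*t ≥ 1`, below which sqrt-scale
  bands are meaningless). It is deliberately a *heuristic envelope*, not a
  calibrated test: the envelope is pointwise-normal in shape but applied
  path-wise, so its nominal level is not 99% in any strict sense. What it is
  good at is what it is used for: a path that flat-lines after a shock leaves
  the envelope decisively, while simulated genuinely-constant paths at
  realistic rates stay inside in ≥ 99% of replicates (checked at λ = 50/day
  over 200 days in the tests). θ is exposed everywhere.
- `z = 1.96` for `forecast_next_year()`, which treats last year's observed
  count per cell as next year's Poisson rate. Bounds reported as counts are
  floored to integers at both ends; with an expected count of 131,478 this
  yields the interval (130,767, 132,188). When a destination grouping is
  supplied, counts are aggregated *before* banding, so regional totals get
  relatively tighter intervals than any cell-wise union would.

`monte_carlo_band()` provides an empirical quantile interval of
`Pois(λt)` draws for small expectations (the normal approximation warns below
an expected count of 30, configurable); it is checked against exact Poisson
quantiles in the tests.

Point expectations shown to humans are rounded half-up (14.009 arrivals/day
reads as 14); raw values are kept everywhere internally.

## The gravity baseline

The comparator allocates arrivals by destination population shares
`P_j / P`, identically for every origin, with no distance term. In
`simulate_flows(model = "gravity")` the Poisson *totals* still come from the
diaspora intensities `ρ R_i t`: the baseline differs only in the allocation
step, so MSE comparisons isolate the assortativity component rather than
conflating it with intensity errors. When diaspora stocks happen to be
proportional to population, the two allocation rules coincide — the regime
where gravity-style models appear to work.

## Simulation and the RNG contract

`simulate_flows()` draws each run as totals-then-allocation; destination
counts sum to the sampled total exactly in every run (an integer identity,
not an approximation). One root seed is supplied; run `k` uses the child seed
`(seed + 1000003·k) mod (2³¹ − 1)`, so an ensemble is bitwise-reproducible,
runs do not share an RNG stream, and any single run can be regenerated
without drawing its predecessors. All package functions restore the caller's
RNG state. Because the generative process being studied resamples both
hierarchy levels, ensembles resample both intensity and assortativity; users
wanting allocation-only variation can condition by fixing totals via
`allocate_destinations()` directly.

## The synthetic-data generator

Register data at this granularity are not public, so `generate_world()`
builds synthetic destination countries with the statistical structure the
model assumes:

- **Destination populations**: Zipf rank-size, exponent 1 (the classical
  city-size value), totalling 9 million — the scale of a mid-sized European
  country.
- **Origin diaspora totals**: Zipf rank-size as well, totalling 1.5 million
  across 20 origins, matching the order of magnitude of a national
  foreign-born register.
- **Per-origin destination distributions**: Dirichlet with parameter vector
  `α · base`, where `base` interpolates (weight `coupling`) between uniform
  and population shares and sums to 1, so `α` is the *total* concentration.
  Small `α` (0.1–0.2) gives near-one-hot, strongly homophilic diasporas;
  large `α` with `coupling = 1` gives diasporas that track population — the
  degenerate regime where gravity and diaspora allocation coincide.
- **Stocks**: each origin's total is placed multinomially by its Dirichlet
  draw; the *realized* shares `R_ij / R_i` are the world's true
  assortativity, so estimation targets are exactly recoverable in principle.
- **Observations**: `generate_observations()` draws daily Poisson increments
  at rate `ρ R_i` and allocates each day's arrivals multinomially; the flow
  matrix is the exact sum of the daily allocations, so generated series and
  flows satisfy the conservation identity to the integer.

Defaults (`world_spec()`): 20 origins, 100 destinations, 200-day window,
ρ = 3.29e-4 per person per day. These echo a national register observed for
roughly half a year and produce on the order of 10⁵ arrivals — enough that
pull-rate recovery within 5% succeeds in well over 95% of seeded replicates
(verified over 200 replicates in the tests).

What the generator does *not* emulate: weekly and seasonal arrival dips,
migration shocks and trends, return migration, stock evolution over the
window, spatial correlation between nearby destinations, and measurement
artefacts of real registers. Passing tests on synthetic worlds therefore
demonstrate internal correctness (estimators recover truth, simulators have
the stated distributions, the model ordering holds when its assumptions do) —
not that the model fits any particular country's data.

## Evaluation choices

`ensemble_mse()` computes, per run, the mean squared cell error over cells
whose *observed* count strictly exceeds the filter (default in the pipeline:
5 — sparse cells carry little signal and dominate relative error), then
reports the per-run distribution and its mean; `mse_ratio()` compares two
models as a ratio of mean MSEs. The strict inequality follows the convention
"arrivals above five"; a consequence is that zero-observed cells are never
evaluated, even at filter 0. Jensen's inequality (ensemble-mean MSE ≤ mean
per-run MSE) is asserted in the tests as a structural sanity check.
`estimate_ratio()` reports per-origin, per-group modeled/observed ratios
(1 = calibrated); groups with zero observed arrivals are flagged `NA`, not
divided.

Problem sizes used in the shipped studies — 200 recovery replicates, 50
concentrated worlds and 10 coupled worlds with 100-run ensembles, 1,000
constant-rate paths — were chosen to give comfortable statistical resolution
for the stated tolerances (e.g. Monte-Carlo error on a 95% pass-rate bound
with 200 replicates is about 1.5 percentage points) while keeping the whole
suite under a minute of compute.

## Known limitations

- The constant-rate envelope is heuristic; users needing a calibrated test
  should use a proper goodness-of-fit procedure on the daily increments.
- Least-squares estimators weight all days/origins equally; a large origin's
  Poisson noise contributes more absolute error, which is harmless at the
  intended scales but makes small-origin rates relatively noisier.
- Zero-diaspora origins are a hard error by design; prediction for such
  origins requires a different mechanism than the one modelled here.
- The gravity baseline is population-share only. It is the appropriate
  comparator for isolating assortativity, but it is not a fitted
  distance-decay gravity model and should not be read as one.
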