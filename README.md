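# diasporaflow

Tools for modelling international migration with the *diaspora model*: a
hierarchical Poisson–multinomial model in which the size of the pre-existing
diaspora is the only covariate. The package is aimed at demographers and
mobility modellers who need to estimate how many migrants will arrive from
each origin and where inside the destination country they will settle, down
to the neighbourhood level, and to compare that against the classical
population-share gravity baseline.

## The model

Migration from origin *i* into a destination country is split into two
components:

- **Intensity** — arrivals follow a homogeneous Poisson process,
  `M_i(t) ~ Pois(λ_i t)`, with `λ_i = ρ R_i`: a single *pull rate* ρ
  (arrivals per diaspora member per day) times the origin's total diaspora
  stock `R_i`.
- **Assortativity** — conditional on arriving, a migrant chooses destination
  *j* with probability equal to the local diaspora share,
  `π_ij = R_ij / R_i`, so `M_ij | M_i = m ~ Mult(m, π_i)`.

By Poisson thinning the two combine into independent cell counts
`M_ij(t) ~ Pois(ρ R_ij t)`, so expected flows are `ρ R_ij t` and aggregate
exactly from postal codes to districts to countries.

Estimators are closed-form least squares:

- per-origin rate from a cumulative arrival series `M(t)`, `t = 0..n`:
  `λ* = 6 Σ_t t·M(t) / (n(n+1)(2n+1))`;
- shared pull rate from per-origin totals and stocks:
  `ρ* = Σ_i M_i R_i / (t Σ_i R_i²)`.

The gravity baseline allocates the same Poisson totals by population shares
`P_j / P`, identical for every origin, which isolates the assortativity
component in model comparisons. A heuristic envelope check
(`λ*t ± θ√(λ*t)`, default θ = 4) flags cumulative paths inconsistent with a
constant rate, and next-year forecasts treat last year's observed arrivals as
next year's Poisson rate with normal bands.

Because national register data of this kind are not public, the package ships
a synthetic-world generator (Zipf destination sizes, Dirichlet-concentrated
diasporas, tunable coupling between stocks and population) so every estimator
and comparison is testable end to end.

## Worked example

```r
library(diasporaflow)

# A 42,580-person diaspora under pull rate 3.29e-4 per person per day:
stocks <- stock_matrix(rbind(PL = c(AT = 42580)))
arrival_rate_from_diaspora(3.29e-4, stocks)
#>       PL
#> 14.00882            # ~14 expected arrivals per day, 2,800 over 200 days

# Next-year forecast from 131,478 observed arrivals, 95% normal band:
fc <- forecast_next_year(flow_matrix(rbind(Africa = c(total = 131478)),
                                     window_days = 365), z = 1.96)
fc
#>   origin destination expected  lower  upper
#> 1 Africa       total   131478 130767 132188

# Full synthetic demo: generate a world, estimate rho, simulate 100-run
# ensembles for both models, compare mean square errors:
res <- run_pipeline(list(seed = 1, runs = 100, out = "demo-out"))
#> synth: 20 origins, 100 destinations, 99116 observed arrivals
#> estimate: pull rate rho* = 0.000329176 per person per day (1 per 3,038 people)
#> constant-rate check (theta = 4): 20/20 origins not rejected
#> evaluate: mean MSE diaspora 1436 vs gravity 3.841e+06 (gravity/diaspora = 2674.06)
```

The demo numbers read as follows: the world was generated with true pull rate
3.29e-4, and the estimator recovers 3.292e-4 from the observed totals; no
origin's cumulative path leaves the θ = 4 envelope, so a constant arrival rate
is not rejected; and because the generated diasporas are concentrated in a few
destinations while the gravity baseline spreads arrivals by population size,
the gravity ensemble's mean square error is orders of magnitude larger. The
MSE ratio collapses towards 1 when stocks are generated proportional to
population (`world_spec(coupling = 1, alpha = 1e6)`).

A command-line interface wrapping the same functions is installed at
`inst/cli/diasporaflow.R` with subcommands `synth`, `estimate`, `simulate`,
`forecast`, `evaluate` and `demo`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "diasporaflow.R", package = "diasporaflow"))')" demo --seed 1
```

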