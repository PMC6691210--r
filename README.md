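# runtiming

Run-timing reconstruction, phenology trend attribution, and hatchery
selection response for sockeye salmon populations supplemented by an
integrated hatchery.

## The problem

Populations of sockeye salmon (*Oncorhynchus nerka*) that mix natural and
hatchery spawning can experience *inadvertent artificial selection* on
reproductive timing: the broodstock weir is installed after the earliest
fish have already entered the river and is shut down by autumn high flows
before the latest fish arrive, while eggs spawned in the hatchery survive
to the fry stage at several times the in-river rate. The result is a
persistent fitness premium for mid- and early-timed fish that can advance
the population's spawn date by days to weeks over a few decades.

This package provides the full analysis chain for quantifying that
process from standard monitoring data (live-fish surveys, hatchery egg
takes, thermally marked otoliths, daily flow and temperature):

* **`run_timing()`** — the central fitted object. Converts one year's
  sparse live-count surveys into a daily entry distribution by linear
  interpolation, the deaths/entries accounting recursion
  (`deaths_t = entering_{t-L}`, `entering_t = live_t − live_{t−1} + deaths_t`
  for stream-life `L`), and an OLS cumulative-normal fit to the cumulative
  entry proportions. Methods: `print`, `summary`, `coef`, `predict`,
  `fitted`, `residuals`, `simulate`, `plot`.
* **`build_covariates()`** — seasonal temperature means/maxima and the
  discharge metrics (Sep–Nov mean, high-flow days above the long-term 75th
  percentile, cumulative September freshet increase).
* **`fit_timing_trends()`** — the 16-candidate suite of
  break-point/trend/covariate Gaussian models, exhaustive break-year
  search, AIC ranking and Akaike weights
  (`w_i ∝ exp(−½ ΔAIC_i)`).
* **`realized_h2()`** — realized heritability of spawn date as the slope
  of standardized offspring-on-parent group means, by age at return.
* **`selection_differential()`, `breeders_equation()`,
  `cumulative_change()`, `monte_carlo()`** — raw and survival-weighted
  selection differentials (`S = raw × (s_h − s_n)/s_h`), the expected
  response `ΔZ = h²S`, its accumulation over realized generations, and a
  10,000-draw Monte Carlo over the uncertain stream-life, delay, and
  survival-advantage parameters.
* **`scenario_config()` / `simulate_scenario()`** — a ground-truth-known
  synthetic generator for every input the pipeline reads, so each stage is
  testable end to end; **`run_pipeline()`** ties the stages into one run
  that writes every table as CSV plus a report.

## Worked example

```r
library(runtiming)

# simulate the reference study system: 25 years, weir truncating the
# late 40% of each run
scn <- simulate_scenario(reference_scenario())

# fit one year's entry distribution from its surveys
fit <- run_timing(scn$surveys[scn$surveys$year == 2005, ],
                  stream_life = stream_life_schedule(18, 11, trend = -2),
                  year_frac = 14/24)
fit
#> River-entry timing model (cumulative-normal fit)
#> Year: 2005
#>   entry mean (mu):   day 265.66
#>   entry SD (sigma):  10.36 days
#>   spawning mean:     day 273.66 (delay 8 d)
#>   reconstructed run: 5.945e+04 fish; fit SSE 0.0396

# propagate parameter uncertainty through the whole selection chain
mc <- monte_carlo(selection_inputs(scn), n_draws = 2000, seed = 42)
mc
#> Monte Carlo selection response: 2000 draws, 21 realized brood years, 5.25 generations
#>        h2  median     q25    q75 prop_negative
#> [1,] 0.30  -4.013  -5.614 -2.323         0.968
#> [2,] 0.50  -6.688  -9.357 -3.872         0.968
#> [3,] 0.83 -11.102 -15.532 -6.428         0.968
```

Reading the output: the fitted entry distribution for 2005 peaks on day
266 (late September) with a 10-day spread; spawning follows 8 days later.
Across 2,000 parameter draws, the hatchery's truncation of the late run
produces a negative cumulative response at every heritability level —
a median advance of ~4, ~7, and ~11 days over 5.25 generations at
h² = 0.3, 0.5, and 0.83 — and about 97% of parameter combinations advance
spawning. `sensitivity(mc)` shows the spawning delay and stream-life
parameters dominate the output variance, with the survival advantage a
distant scale factor.

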