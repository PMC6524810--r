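# effortseas

Seasonality analysis of gridded industrial fishing effort.

Satellite AIS tracking, run through fishing-detection models, yields
daily records of which vessels fished where. `effortseas` turns such
per-vessel daily records into gridded **vessel-day** effort (one vessel
fishing at least once in one cell on one day) at 0.5°, 1.0° and 4.0°
resolution, and characterizes when and where fishing is seasonal. It is
aimed at fisheries scientists and spatial ecologists who want the full
chain — ingest, gridding, seasonal statistics, validation — as tested,
scriptable R functions rather than one-off analysis code.

## What it computes

With `e_g(i,j)` the monthly vessel-day sum of gear `g` in cell `(i,j)`
divided by the days in the month, and `E_g = Σ_{i,j} e_g(i,j)` its
global sum:

- **Global series and shares** — `E_g` per month, its relative variation
  `E_g/Ē_g` (mean 1 by construction) with the sample sd as the intensity
  of each gear's seasonal cycle, and percentage gear shares.
- **Implied holiday days** — for a winter month at fraction `f` of the
  March–November baseline, `(1 − f) × days(month)` implied non-fishing
  days, signed, computed after removing a masked EEZ.
- **Seasonality index** — per cell, on the 12-month climatology `e_n`
  with annual total `a`: `SI = (1/a) Σ_n |e_n − a/12|`, ranging 0
  (uniform) to 22/12 ≈ 1.83 (all effort in one month); equal effort in
  `k` months gives exactly `2(12−k)/12`.
- **Peak month** — per cell, the argmax of the first right-singular
  vector of the grand-mean-centered year × month matrix, for cells
  active in every year whose first mode explains ≥ 2/3 of the variance.
- **Dominant gear** — the gear holding strictly more than 75% of a
  cell's window-summed effort, if any.
- **Distance-to-port profiles** — effort-weighted mean of the local
  relative sd per 75 km bin of distance to the nearest port, discarding
  bins below 0.1% of a gear's annual effort.
- **Synthetic data with ground truth** — a parametric AIS-like generator
  (gear-specific spatial fields, cosine seasonal cycles with controlled
  peak and amplitude, an EEZ moratorium, holiday deficits, Poisson
  vessel-day sampling, vessel metadata) and a bioeconomic simulator
  `dE/dt = κ_e(pqB − c)E − R` with harvest `H = qEB`, so every estimator
  can be validated end to end.

## Worked example

Simulate three years of records with known structure, run the chain,
and compare with what was injected (shares 53/15/13/11·0.55/11·0.45/4/4,
holiday deficits 4/4/2.5 days, a May–September moratorium in the
coastal EEZ band):

```r
library(effortseas)

scn     <- synthetic_scenario(seed = 42)
sim     <- generate_parametric(scn)
records <- filter_continuous_vessels(sim$records, 2015:2017)
vessels <- split_purse_seiners(sim$vessels)

grid  <- grid_spec(1.0)
daily <- rasterize_daily(records, vessels, grid)
meg   <- monthly_aggregate(daily, grid,
                           coverage = as.IDate(c("2015-01-01", "2017-12-31")))
total_vessel_days(meg)
#> [1] 307522

round(gear_shares(global_series(meg)), 1)
#> drifting_longlines         fixed_gear              other      purse_coastal
#>               17.1               13.3                5.4                5.4
#>    purse_high_seas       squid_jigger           trawlers
#>                6.5                5.2               47.1

eez        <- generate_eez_mask(scn)$mask
open_ocean <- apply_mask(meg, eez, mode = "remove")
implied_holiday_days(global_series(open_ocean))
#> Baseline (Mar-Nov mean total effort): 98.788 vessel-days/day
#>   month 12: 3.8 implied holiday days
#>   month  1: 3.6 implied holiday days
#>   month  2: 2.4 implied holiday days

si <- seasonality_index(climatology(meg))
summary(si$data$si)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.2384  0.3836  0.4331  0.4579  0.4979  0.8065
```

The realized shares differ from the nominal 53/15/… because the
moratorium and holidays remove effort unevenly across fleets — the
generator's truth record (`sim$truth$expected_fleet_shares`) accounts
for this, and the estimates above match it to Poisson sampling error.
The holiday estimates recover the injected 4/4/2.5 days to a few tenths
under Poisson noise, and exactly on noise-free expectations.

The same chain runs from a shell:

```sh
Rscript inst/cli/effortseas.R all --config run.yaml --seed 42 --out out/
```

with subcommands `simulate`, `ingest`, `global-stats`, `local-stats`,
`port-stats` for stage-wise reruns from the files alone.

## Layout

- `R/` — ingest and gridding, masks, global metrics, local (per-cell)
  metrics, distance-to-port profiles, the synthetic generator, the
  bioeconomic simulator, the pipeline.
- `tests/testthat/` — unit and property tests per module plus the
  end-to-end validation suite.
- `vignettes/effort-seasonality-methods.Rmd` — the methods vignette:
  models, conventions, generator design, numerical choices,
  limitations.
- `inst/cli/effortseas.R` — command-line front end.
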