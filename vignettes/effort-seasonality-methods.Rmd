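---
title: "Methods: gridded fishing-effort seasonality"
author: "effortseas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded fishing-effort seasonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortseas)
library(data.table)
```

## The measurement model

The atomic unit of effort is the **vessel-day**: one vessel detected
fishing at least once in one grid cell on one calendar day. Daily
per-vessel records (`vessel_id, date, lat, lon, is_fishing`), as produced
by AIS-based fishing-detection pipelines, are deduplicated per
(vessel, cell, date) and counted; a vessel visiting several cells on one
day contributes one vessel-day to each of them, because counting is
defined per grid cell and cross-cell deduplication would make cell counts
mutually dependent. Grids are plate carrée at 0.5, 1.0 or 4.0 degrees,
addressed by lower-left corner on half-open intervals, so every point on
Earth — including longitude 180, which wraps, and the pole rows — maps
to exactly one cell.

Monthly local effort is the vessel-day sum over a month divided by the
number of days in that month (29 for leap Februaries), in
fishing-vessel-days per day. This normalization makes months comparable;
multiplying back by month lengths and summing recovers the retained
vessel-day count exactly, a conservation identity asserted throughout
the tests.

Two filters precede gridding. The **continuity filter** keeps only
vessels with at least one fishing record in every calendar year of the
window (2015–2017 by default) — the weakest reading of "continually
active" implementable from effort records alone; stricter windows can be
passed. The **purse-seine split** classifies a purse seiner as high-seas
iff its length exceeds 40 m *and* the mean distance of its fishing
positions from shore exceeds 50 nm (1 nm = 1.852 km); a missing length
conservatively yields the coastal class, which is the majority class, so
the high-seas fleet is never silently inflated.

## Seasonality statistics

**Global series.** Per gear g and month, E_g is the globally summed
daily-mean effort; the total is E = Σ_g E_g. The relative series
E_g / Ē_g (Ē_g the full-window mean) has mean one by construction and
its sample standard deviation (n − 1 convention) measures the intensity
of each gear's seasonal cycle. Gear shares are window sums of E_g as
percentages of the total.

**Implied holiday days.** The baseline is the mean total monthly effort
over all March–November months, computed after removing the
moratorium-affected EEZ. For a winter month m, the implied number of
holiday days is (1 − E_m / baseline) × days(m), evaluated per year with
that year's month length and averaged per calendar month. Estimates are
signed: a busier-than-baseline month yields negative days, so generator
or pipeline errors cannot hide behind clipping. The statistic is
invariant under uniform rescaling of effort.

**Seasonality index.** For a cell's 12-month climatology e_n (the mean
across years of each calendar month, with absent months counted as
zero), with annual total a = Σ_n e_n,

SI = (1/a) Σ_{n=1..12} | e_n − a/12 |.

SI is 0 for perfectly even effort and 22/12 ≈ 1.83 when all effort
falls in one month; effort spread equally over k months gives exactly
2(12 − k)/12, a closed-form ladder the tests verify against a direct
evaluation. The normalizer a is the annual *total* of climatological
months — with an annual *mean* the maximum would be 22, inconsistent
with the 0–1.83 range the statistic is designed for. SI is invariant
under positive rescaling of a cell's series and undefined (flagged)
where the annual total is zero. The headline map uses all-gear summed
effort; per-gear maps are available on demand.

**Local relative standard deviation.** Per gear and cell, the sample sd
of the full monthly series (absent months as zero) divided by the
window-mean monthly effort; undefined where the mean is zero.

**Peak month.** On all-gear summed effort, each cell's year-by-month
(Y × 12) matrix is grand-mean centered and decomposed by SVD. A cell
passes when (1) its annual total is nonzero in every year and (2) the
first singular mode explains at least 2/3 of the variance
(σ₁²/Σσ_k²). The climatological component is the first right-singular
12-vector, sign-chosen to correlate positively with the cell's mean
monthly profile, and the peak month is its argmax with ties broken to
the earliest month. The matrix layout, centering, sign convention and
tie-break are deliberate choices: the procedure as usually described
("climatological first principal component") does not pin them down, and
this variant is deterministic and testable. Cells whose centered matrix
is numerically zero fail the variance filter with a recorded
`degenerate` status. Cells with identical rows (years) always pass with
explained variance 1, since after centering all variation is seasonal.

**Distance-to-port profiles.** Distance to the nearest port is
bilinearly interpolated from a fine raster at each cell center (invalid
corner nodes are dropped and the weights renormalized; cells outside the
raster or with all-invalid neighborhoods are flagged and excluded). Per
gear and contiguous 75 km half-open bin, the profile is the mean local
relative sd over the bin's cells weighted by their annual climatological
effort; bins carrying less than 0.1% of the gear's global annual effort
are flagged discarded (values still computed). Both the weights and the
threshold scale with effort, so profiles are invariant under uniform
rescaling. The bin width and discard fraction are configurable. Where no
separate shore raster is supplied, the port raster stands in for the
purse split with a warning.

## The synthetic generator

Because the real AIS dataset is large and external, validation runs on
a generator whose every parameter is known. The default scenario is a
30° × 24° ocean basin on a 1° grid (longitudes 0–30, latitudes −12–12)
with a meridional coastline on the western edge, three ports on the
coast, and years 2015–2017. Seven fleets carry the observed effort
shares — trawlers 53%, fixed gears 15%, drifting longlines 13%, purse
seiners 11% (split 55% coastal / 45% high-seas), squid jiggers 4%,
other 4%. Coastal fleets (trawlers, fixed gears, coastal purse seiners)
decay exponentially from shore (e-folding 150 km, hard limit 600 km);
the remaining fleets cover the basin uniformly. The domain totals
400 expected vessel-days per day across 60 vessels per fleet — large
enough that monthly Poisson noise sits near the few-percent level where
the statistics are informative, small enough that a full record stream
(~0.3 M records) generates and processes in seconds.

Each cell carries a cosine seasonal cycle
1 + A·cos(2π(m − peak)/12) with amplitude A = 0.6 by default and a peak
month that cycles through the twelve months across latitude bands —
seasonal timing varying with latitude, as it does for migrating prey.
The 24-row latitude span makes the twelve phase bands exactly balanced,
and with `conserve_global = TRUE` the forcing is renormalized per fleet
and month over the open-ocean (non-EEZ) cells, so seasonality
*redistributes* effort spatially while each fleet's deployment outside
the closure region stays constant month to month. This emulates the
central empirical pattern the statistics are designed to detect —
near-constant global deployment with strong spatial shifts — and makes
the holiday estimator exactly invertible on noise-free data.

Societal forcing enters as (a) whole-day **holiday deficits** in
December/January/February (defaults 4.0, 4.0 and 2.5 days, applied as a
uniform within-month reduction of 1 − h/days(m)), and (b) a
**moratorium** that zeroes effort inside the coastal EEZ band
(longitudes 0–4, the ~200 nm jurisdiction strip along the coast) during
the observed closure windows: May 16–September 16 in 2015 and 2016,
May 1–September 16 in 2017.

Noise modes: `"poisson"` draws vessel-day counts per fleet, cell and
month around the expectation; `"gaussian"` adds monthly noise scaled by
the cell's seasonal oscillation amplitude (A × base level), the natural
unit for peak-recovery experiments; `"none"` returns the expectation.
Records mode spreads monthly counts uniformly over the month's open
days, assigns them to distinct vessels within each cell-day, relabels
records of busy fleet-mates so every regular vessel has at least one
record per year (the continuity filter keeps them all), and jitters
positions uniformly within cells. Optional dropout vessels active only
in the first year exercise the filter. Identical scenario and seed give
byte-identical outputs.

Two subtleties discovered during validation are worth recording. First,
holiday deficits genuinely displace the realized peak of winter-peaking
cells — the injected cosine phase and the argmax of the expected
climatology then differ, so the truth record stores both (`peak` and
`expected_peak`) and recovery is judged against the latter. Second, on
domains whose row count is not a multiple of twelve the redistribution
normalizer wobbles by a few percent per month, creating near-ties
between adjacent months in realized profiles. Peak-recovery experiments
therefore isolate the seasonal signal: holidays and moratorium off,
`conserve_global = FALSE`, gaussian noise at 5% of the seasonal
amplitude. Under those conditions the injected peak is recovered in
essentially all cells; the analysis of the near-tie geometry, not a
threshold search, motivated the design.

The distance rasters are exact great-circle (haversine, R = 6371 km)
distances to the nearest port and to the coastline on a 0.1° grid —
fine enough that bilinear interpolation at 1° cell centers is accurate
to a few kilometres, coarse enough to stay small.

**Bioeconomic mode.** Effort can instead evolve dynamically per cell as

dE/dt = κ_e (p q(t) B(t) − c) E − R(t),  E ≥ 0 (clipped),

the profit-per-unit-effort form of a fleet-dynamics model with harvest
H = qEB: revenue per unit effort p·H/E = p·q·B against cost c, with
regulation R removing effort inside the closure region during closure
windows. All rates are per day; integration is daily explicit Euler,
whose O(Δt) error is verified against the exponential (constant profit)
and linear-decline (pure regulation) closed forms. Catchability and
biomass accept cosine seasonal forcing. A thinning step emits Poisson
vessel-day records from the simulated field.

## Numerical choices and degenerate inputs

- Standard deviations use the sample (n − 1) convention everywhere.
- Mask membership is by cell center in polygon (mgcv's ray-crossing
  test); fractional-overlap weighting was rejected as over-engineering
  for 1° analysis cells.
- Gridded interfaces are long-format CSV (`gear,year,month,lon,lat,
  effort_per_day` and analogues), the package's canonical exchange
  format; masks are GeoJSON polygons or cell-center CSVs.
- Zero-mean cells, zero-effort gears, empty masks and empty bins are
  flagged or excluded with warnings, never silent errors; a zero
  baseline or zero total effort is a hard error because the requested
  statistic is undefined.
- More than 50% rejected input rows aborts ingestion — a stream that
  degraded is better refused than summarized.
- All randomness flows from a single seed; identical configuration and
  seed reproduce every output digest bit for bit (asserted in tests).

## Problem sizes

The test and validation suites run the default 720-cell scenario
(~0.3 M records over 36 months), a 900-cell peak-recovery scenario, 20
Poisson replicates for holiday/share recovery and for distance-gradient
monotonicity, 1000-cell Monte-Carlo nulls for the variance filter, and
the three-resolution harness (0.5°/1°/4°) on one record stream. These
sizes put Poisson sampling error near the few-percent level — large
enough to exercise every estimator's stochastic behaviour, while the
whole suite completes in well under five minutes on a single core.

## What passing tests do and do not show

The generator emulates gear-specific spatial structure, per-cell
seasonal cycles with known phase, a regional moratorium, holiday dips
and Poisson vessel-day sampling. It does *not* emulate AIS coverage
bias, satellite gaps, vessel kinematics within a day, fleet entry/exit,
multi-peak seasonal cycles, or spatially correlated noise. Recovery of
injected structure therefore validates the estimators' correctness, not
the representativeness of any real dataset; headline numbers from the
real 2015–2017 AIS analysis (gear shares, per-gear sd values, cell
retention rates) depend on that data and are not reproduced here. The
peak-month procedure resolves a single dominant cycle; cells with
genuinely multi-modal seasonality fail the variance filter or report
the stronger mode only.
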