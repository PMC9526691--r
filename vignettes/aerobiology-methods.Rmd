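---
title: "Methods: pollen seasons, calendars and wind source-receptor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen seasons, calendars and wind source-receptor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeropollen)
```

This vignette documents the statistical methods the package implements, the
choices made where conventions in the aerobiological literature are loose,
and what the synthetic-data validation does and does not demonstrate.

## From slide counts to concentrations

A Hirst-type volumetric trap draws air at a known flow rate (10 L/min for
the standard instrument) onto an adhesive tape cut into daily slides. Only a
fraction of each slide is counted under the microscope — typically four
horizontal transects covering 12–13% of the surface. The daily concentration
is

$$C = \frac{\text{count}}{f \cdot V}, \qquad V = \frac{\text{flow rate (L/min)} \times \text{minutes}}{1000} \ \text{m}^3,$$

with $f$ the counted fraction. The default $f = 0.125$ is the midpoint of
the 12–13% range; it is a `trap_config()` parameter because tape geometry
varies between laboratories and the exact factor should always be stated
with the data. Counts are non-negative by construction and the conversion is
linear in the count and inversely linear in $f$ and the flow rate — these
are asserted as properties in the test suite.

Missing days are stored as `NA`, never imputed at ingestion, and kept
distinct from true zeros; each downstream stage documents its own
missing-data rule.

## APIn and the 90% Main Pollen Season

The Annual Pollen Integral is the season's total exposure in
pollen·day/m³. With complete data it is the plain sum of daily
concentrations; with gaps the recommended convention multiplies the mean
observed daily concentration by the number of calendar days in the period.
Both are exposed (`method = "mean_by_days"` is the default, `"sum"` the
alternative) because the literature wording covers the former while many
stations compute the latter; they coincide exactly on complete years.

The Main Pollen Season is delimited by the 90% method: with daily values
$c_1, \dots, c_{365}$ and total $T$, the season starts on the first day $d$
with $\sum_{i \le d} c_i \ge 0.05\,T$ and ends on the first day reaching
$0.95\,T$. Three conventions needed fixing:

- **Threshold crossing uses $\ge$** (the first day *reaching* the quantile).
- **Duration is the exclusive difference** end − start in calendar days, not
  the inclusive day count. Both choices were verified jointly against
  published season tables: nine independently printed (start, end, duration)
  triples are reproduced integer-exactly by `season_duration()`, which would
  fail systematically (off by one) under the inclusive convention.
- **Missing days contribute zero** to the cumulative sum. This biases the
  delimitation only when gaps fall inside the season; a year with more than
  25% of days unmonitored carries a `quality_warning` flag instead of a
  hard failure, since late trap deployments are common in real campaigns.

A year with zero total yields a `season_defined = FALSE` row, not an error,
so multi-taxon tables degrade gracefully. Peak ties break to the earliest
date, keeping output deterministic. The implementation is checked against a
brute-force cumulative scan on 1,000 random series, and on noisy synthetic
seasons (below) the recovered start and end are within a median of 1 day of
the noise-free truth whenever the daily peak reaches 100 grains/m³.

## Pollen calendar

The calendar is built from a multi-year **daily climatology**: the mean
concentration per calendar day (month, day) across the years in which that
day was observed, with 29 February averaged only over leap years. Flowering
intervals are computed on the climatology, not per year and then averaged,
because the calendar is a property of the averaged year.

Each month is split into five sections. "Five sections of six days" cannot
hold for 28/29/31-day months, so sections 1–4 are exactly days 1–6, 7–12,
13–18, 19–24 and **section 5 absorbs the remainder** (4–7 days). This keeps
sections 1–4 comparable across months and makes the section decomposition
exactly conservative: the section-length-weighted mean of the 60 section
means equals the climatology's annual mean to machine precision (asserted
at $10^{-9}$).

Day classes follow the cumulative fraction $F(d)$ of the climatological
annual sum: the **main** flowering period runs from the day $F$ first
reaches 10% through the day it first reaches 90% (both inclusive — the
boundary day on which a threshold is crossed belongs to the interval it
opens or closes); **early** days precede the main period with $F > 0.5\%$;
**late** days follow it with $F < 99.5\%$; any other day with a positive
climatology mean is a **possible** occurrence; the rest are **none**. On a
uniform 100-day fixture this yields early days 1–9, main 10–90, late 91–99
and possible day 100, enumerated in the tests. A calendar cell takes the
highest-ranked class among its days (main > late > early > possible >
none), so a section containing any main-period day displays as main.
Whether "pollen observed" for the possible class should use a strict
positivity test or a minimum-count rule is not settled in the literature;
strict positivity is used. Allergenicity classes are user configuration — a
literature judgement, not a data product — shipped as an editable table in
`inst/extdata/allergenicity.csv`.

## Diurnal profiles

`mean_hourly_profile()` averages hourly concentrations by hour of day.
Percent-of-daily-total is the default mode: each day is normalised to 100%
before averaging, so the diurnal *shape* is not dominated by a few
high-concentration days; zero-total days are excluded (their shape is
undefined) and days with fewer than 12 observed hours do not qualify.
Absolute mode reproduces raw mean curves. `peak_window()` reports maximal
contiguous hour ranges at ≥ 80% of the profile maximum, wrapping across
midnight, so bimodal diurnal patterns (a morning and an evening peak) are
reported as two windows rather than flattened into one.

## Pollen–meteorology screening

Daily pollen concentrations are strongly non-normal (zero-inflated,
right-skewed), so the association analysis is rank-based throughout. The
Lilliefors test is provided as a screening report (`lilliefors_test()`,
analytic p-values via nortest, with a seeded Monte-Carlo alternative whose
null regenerates the statistic on standard-normal samples); the pipeline
does not branch on its outcome.

Spearman's ρ is the Pearson correlation of average ranks with the
t-approximation ($n-2$ df) for the p-value. Correlations are computed only
on days inside each taxon's MPS (`mps_correlation_matrix()`) — outside the
season the concentration is structurally zero and would manufacture
spurious associations — and per calendar month for total pollen
(`monthly_correlation()`), where months with fewer than 10 complete pairs
are skipped: below that, rank correlations are noise. α = 0.05 with no
multiple-testing correction matches per-pair reporting practice in the
field; a Benjamini–Hochberg option exists but is off by default. Degenerate
inputs (constant parameter, fewer than 3 pairs) yield flagged undefined
results, never silent drops: the output always contains one row per
(taxon, parameter).

## Wind source-receptor analysis

The single-pass **Yamartino estimator** of the wind-direction standard
deviation is, with $\bar s, \bar c$ the means of $\sin\theta_i, \cos\theta_i$
and $\varepsilon = \sqrt{1 - (\bar s^2 + \bar c^2)}$,

$$\sigma_\theta = \arcsin(\varepsilon)\,\bigl[1 + (2/\sqrt{3} - 1)\,\varepsilon^3\bigr],$$

bounded by $90 \cdot 2/\sqrt{3} \approx 103.92^\circ$. It agrees with a
two-pass circular standard deviation within 2% over the spreads tested.

**NWR** estimates the expected concentration at a (direction $\theta$,
speed $v$) grid point as the kernel-weighted mean
$\hat C(\theta, v) = \sum_i w_i C_i / \sum_i w_i$ with
$w_i = \exp\!\bigl[-\tfrac12 (\Delta(\theta, \theta_i)/h_\theta)^2\bigr]
\exp\!\bigl[-\tfrac12 ((v - v_i)/h_v)^2\bigr]$, where $\Delta$ is the
wrapped angular distance. **SWIM** multiplies each observation's weight by
$\bar\sigma / \sigma_i$, up-weighting sustained (low directional
variability) winds, and optionally max-normalises the surface to $[0,1]$.
One widely circulated statement of the SWIM formula glosses its symbols
inconsistently with the NWR literature it derives from (labelling the
concentration term as wind speed); this package follows the original
construction — $C_i$ is the measured concentration, the kernel carries the
wind geometry, and $\bar\delta/\delta_i$ is an observation weight — which is
the only reading under which the method estimates a concentration surface.

Defaults ($h_\theta = 15^\circ$, $h_v = 2$ km/h, 72 direction bins, 0.5 km/h
speed steps) give ZeFir-like smoothness and are fully configurable. Cells
receiving total kernel weight below 0.1 are undefined rather than
extrapolated. $\sigma_i = 0$ (perfectly steady wind) would give infinite
weight and is replaced by the smallest positive sigma observed, with a
warning. Every estimate is a convex combination of the input
concentrations, asserted as a property. Compass sectors are centred on the
compass points (N spans −22.5° to 22.5° with 8 sectors), the meteorological
convention; ties in `dominant_sector()` break to the lowest speed band and
then the first sector clockwise from North. Wind speeds are km/h internally
(`knots_to_kmh()` converts the 1 kt = 1.852 km/h service data).

## Synthetic data: what it emulates and what it does not

The generators produce the statistical structure the analysis assumes, with
ground truth recorded alongside:

- `generate_taxon_year()`: a gamma-shaped unimodal daily mean curve (rapid
  rise, slower decay, matching the right-skew of observed season curves),
  scaled so the noise-free annual sum equals the target APIn, with
  negative-binomial daily noise. Aerobiological counts are overdispersed, so
  Poisson noise would understate day-to-day variability; the dispersion is a
  parameter and `Inf` gives the noise-free limit. The default bundle of six
  taxa takes its timing and APIn magnitudes from a typical urban Irish
  pollen year — early Alnus, mid-April Betula/Fraxinus, May Quercus, then
  much larger June–August Poaceae and Urticaceae seasons — so the summed
  total is bimodal with the summer mode higher.
- `generate_wind_with_plume()`: uniform directions, Weibull(2, 8 km/h)
  speeds, and concentrations elevated only when the wind samples a planted
  (direction ± spread, speed band) source.
- `generate_meteo_with_association()`: a Gaussian-copula blend of the pollen
  ranks with noise, with the normal-scale correlation calibrated as
  $2\sin(\pi\rho_S/6)$ so the realised Spearman correlation approximates the
  target on continuous series; targets ±1 return exactly co-monotone
  transforms. The realised ρ is recorded as ground truth because heavy ties
  (long runs of zero days) attenuate any rank association — a property of
  rank statistics, not of the generator — so calibration checks use
  continuous series.
- `generate_hourly()`: multinomial allocation of each day's total across
  hours by a template, preserving daily sums up to rounding.

Problem sizes used in the validation suite — 365-day years, 36 season
recoveries, 20 plume recoveries, 100-seed correlation calibrations, 1,000
series for the delimitation oracle — were chosen so each check has clear
resolution at its stated tolerance while the whole suite runs in well under
a minute.

What passing these checks does **not** show: real pollen series have
autocorrelated weather-driven noise, multi-day rain washout, resuspension
events and occasional long-range transport spikes, none of which the
generators emulate; real wind-pollen coupling is confounded with season
phase (sources "appear" only while flowering); and trap efficiency varies
with particle size and wind speed. The synthetic validation demonstrates
correctness of the computations under their stated assumptions, not field
accuracy.

## Known limitations

- Only the quantile-pair family of MPS definitions is implemented
  (configurable via `season_method_config()`); threshold-day and
  logistic-fit definitions are out of scope.
- Hours are local clock hours as recorded; no daylight-saving adjustment.
- The per-day Yamartino sigma must be computed from whatever within-day
  direction samples the user has; sub-hourly source data formats are not
  parsed.
- Back-trajectory (transport-model) attribution is out of scope: the
  source-receptor module infers wind sectors, not emission locations.
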