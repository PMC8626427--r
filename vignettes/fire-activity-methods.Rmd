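---
title: "Methods: burned-area accounting, YSLF reconstruction and fire-weather indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burned-area accounting, YSLF reconstruction and fire-weather indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firetrends)
```

This vignette is the package's own account of its methods: the models and
conventions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices made where the
design was genuinely open, and the known limitations.

## The analysis problem

Multi-decadal fire-activity analysis for forest ecosystems rests on three
data streams: annual fire histories from land-management agencies
(polygon perimeters with a wildfire/prescribed cause attribute,
rasterized), monthly satellite burned-area products, and daily gridded
weather. The quantities of interest are per-fire-year burned-area series,
the per-pixel number of years since the last wildfire (YSLF), daily
fire-weather indices and their threshold-day counts, and regression
models linking burned area to fire weather. This package implements each
stage on plain regular latitude–longitude grids (R matrices plus an
explicit `grid_spec`), with text-based raster I/O; no projected
coordinate systems are supported, and the GDA94/WGS84 datum offset
(< 2 m) is ignored as sub-pixel at the working resolutions of 0.0025°
and 0.01°.

## Fire years, seasons, and union accounting

Fire years run July–June, labelled by the July calendar year, so the
Austral summer (DJF) sits inside one accounting period. Seasons are the
Austral meteorological seasons; autumn + winter is the March–August cool
season. Annual burned area is the area of the union of burned ∩ forest
cells over the fire year's 12 months: a cell that burns in October and
again in January is flagged but **not recounted**.

Seasonal attribution of a multi-burn cell was an open choice; we
attribute it to its *first* burn month of the fire year, which preserves
the union accounting exactly (the four seasonal areas always sum to the
annual area). The alternative — counting the cell in every season it
burned — would make seasonal totals exceed the annual union and was
rejected for that reason. Incomplete trailing fire years are an explicit
error unless `keep_partial = TRUE`, so trend inputs cannot silently
include partial years.

Cell areas use the spherical-Earth closed form
$R^2\,\Delta\lambda\,(\sin\varphi_{top}-\sin\varphi_{bot})$ with
$R = 6371$ km; a 0.01° cell at the equator is 1.2364 km², the nominal
"1.1 km × 1.1 km" AVHRR-class pixel. The formula telescopes, so cell
areas aggregate exactly across resolutions. Forest masks are
majority-resampled (> 50 % of fine cells; an exact 50 % tie resolves to
non-forest — the conservative choice, since the convention is not
standardised). Perimeter rasterization marks cells whose *centre* falls
inside a polygon, with boundary points counted inside; the edge
convention is a deterministic choice, not an inference, and vertex
order/winding cannot affect the result (even-odd rule).

## YSLF reconstruction and the geometric initializer

For each pixel with at least one recorded wildfire, the mean annual fire
frequency is estimated from its own record, $\hat p = k/n$ over $n$
record years (prescribed burns excluded throughout). Pixels burning in
the origin year start at YSLF = 0. Every other eligible pixel draws its
unknown pre-record state from the geometric quantile function

$$\mathrm{YSLF}_0 \;=\; \left\lceil \frac{\ln(1-u)}{\ln(1-\hat p)} \right\rceil,
\qquad u \sim \mathrm{Uniform}(0,1),$$

which yields $P(k) = \hat p\,(1-\hat p)^{k-1}$ on $\{1, 2, \dots\}$ —
the stationary distribution of time since the last event of a
Bernoulli($\hat p$) process, conditional on no event in the origin year.
Whether the bracket denotes ceiling, floor or rounding was open; we chose
**ceiling** because it is the proper geometric quantile on
$\{1,2,\dots\}$, and because floor would produce 0 for small $u$,
colliding with the code reserved for pixels that actually burned in the
origin year. `geometric_init(rounding =)` exposes the alternatives for
sensitivity analysis. Surfaces increment by one per year and reset to
zero at recorded fires; a provenance flag flips from "estimated" to
"observed" at a pixel's first in-record fire, and observed values are
seed-independent by construction.

Decadal summaries report the mean and SD of the decade's ten annual
spatial means over eligible pixels. Whether published decadal SDs of
this kind are across years or across pixels is ambiguous in general; the
across-year reading produces SDs of order 0.1–10 years (per-pixel SDs
would be tens of years) and is the default, with `pixel_sd = TRUE`
available. Spatial means are unweighted pixel counts by default with an
area-weighting option, since pixel weighting conventions also vary.

Two conditioning effects matter when validating against the stationary
expectation $(1-p)/p$:

* eligibility (at least one fire in the record) removes the
  longest-unburned pixels, biasing the mean slightly *downward*;
* initializing from the pixel's own $\hat p$ rather than the true $p$
  inflates initializer draws for low-frequency pixels
  ($E[1/\hat p \mid k \ge 1] > 1/p$), biasing the early-record mean
  slightly *upward*.

Both effects are part of the defined method, so our tests validate
against a Monte-Carlo oracle that simulates the same procedure through an
independent code path (closed-form last-burn bookkeeping with an
`rgeom`-based initializer at $\hat p$) rather than against $(1-p)/p$
directly. At $p = 0.05$ over 90 years the final-decade eligible-mean sits
near 18.2 years against the unconditional 19.

## Fire-weather indices

All index coefficients live in one constants table (`R/constants.R`)
with their published sources; none are repeated inline.

**KBDI** (0–203.2 mm soil-moisture deficit): daily rainfall first fills
a 5.08 mm interception allowance per rain event — consecutive wet days
share one allowance, carried explicitly through the recursion — and only
the excess reduces the index; the daily evapotranspiration increment
depends on the running index, the day's maximum temperature and mean
annual rainfall. The index is clamped to [0, 203.2] for any input
sequence. Note the wet steady state is marginally above zero because the
ET increment applies after same-day rain.

**Drought factor** (0–10): the Griffiths limiting form, driven by KBDI
and the recency ($N$ days) and size ($P$ mm) of the last significant
(≥ 2 mm) rain event through
$x = N^{1.3}/(N^{1.3} + P - 2)$, capped at 10. It is non-decreasing in
KBDI and in days-since-rain.

**FFDI**: the McArthur Mark 5 meter equation
$\mathrm{FFDI} = 2e^{-0.450 + 0.987\ln DF - 0.0345\,RH + 0.0338\,T + 0.0234\,V}$,
with the $DF = 0$ singularity defined to 0 (no available fuel). Published
gridded FFDI datasets are typically calibrated against operational fire
weather forecasts; that calibration is not public and is not reproduced —
this package computes the standard meter. Threshold comparisons are
inclusive (≥ 25 Very High, ≥ 50 Severe).

**C-Haines**: stability $CA = 0.5(T_{850}-T_{700}) - 2$; humidity from
the 850 hPa dewpoint depression $DD$ capped at 30 °C,
$CB = DD/3 - 1$ with the excess above 5 halved. $CA$ depends only on the
lapse and $CB$ only on the depression — the index is not invariant to
adding a constant to both temperatures at fixed dewpoint, which is why
the components are tested separately.

**Dry lightning**: lightning day with rainfall < 2.5 mm.

**Day counts**: the default mode reduces each day's field to its spatial
mean over the forest mask and thresholds that single series (one
national/regional index day), because published day-count series are
single curves per threshold; a per-pixel exceedance mode (count per
pixel, then average) is provided since the aggregation order is often
unstated, and the mode is recorded in the output.

**Epoch changes**: per-pixel mean(2000–2019) − mean(1980–1999) by
default, with the dry-lightning epoch ending in 2016 where that record
ends; occurrence fields also report the relative frequency change in
percent.

## The statistical layer

"Exponential fit" means OLS on the log response (not nonlinear least
squares): growth rate $e^{b}-1$ per year, or per threshold-day for the
burned-area ~ fire-weather regression (a slope of $\ln 1.21$ reads as
21 % more burned area per additional FFDI ≥ 25 day). The year index is
centred before fitting for conditioning and coefficients are
back-transformed. Zero burned-area values cannot enter a log fit and are
excluded with a message and a recorded count. p-values are classical
two-sided OLS t-tests with no autocorrelation correction, matching common
practice for these series; a lag-1 Newey–West robust option exists but is
off by default. A numerically constant response is reported as slope 0
with p = 1 rather than whatever floating-point noise `lm` happens to
produce. Percent change between record halves is
$100(\bar y_2/\bar y_1 - 1)$, so a five-fold increase reads as +500 %.
The multivariate model decomposes $R^2$ sequentially in the order the
predictors are given (fire-weather first by convention) and reports the
pairwise predictor correlations, because the typical finding — added
predictors contribute marginally — is driven by their collinearity with
the leading index. Held-out prediction is $\exp(a + bx)$ with no
lognormal bias correction by default (the correction is available); out
of range predictors warn rather than error, because predicting a record
season from a model fitted to ordinary ones is an extrapolation by
construction.

## The synthetic-data generator

The generator defines the conditions under which everything is tested.

* **Fire process**: independent Bernoulli($p$) per pixel-year, one
  wildfire at most per pixel per year (matching annual fire-history
  resolution); double burns exist only in the monthly product layer.
  Defaults are stationary so closed forms hold: mean YSLF $(1-p)/p$,
  burned-at-least-once fraction $1-(1-p)^n$. An optional logistic
  coupling, off by default, modulates $p$ by a standardized annual
  fire-weather summary.
* **Prescribed burns**: a separate cause layer hitting a Gaussian annual
  area target (truncated at 0), placed uniformly at random.
* **Weather**: per-variable seasonal cycle (cosine, hottest mid-January;
  humidity and rain peak mid-July) + linear trend (per decade) + Gaussian
  noise, with physical clamps (RH ∈ [0, 100], rain ≥ 0,
  $T_{d,850} \le T_{850}$ via a non-negative generated dewpoint
  depression). A `synoptic_share` (default 0.8) of the noise variance is
  shared across the grid each day, because weather systems are larger
  than analysis domains; without it, spatial averaging would remove all
  extreme fire-weather days, which no real record does.
* **Monthly product**: each pixel-year fire is dated into one month of
  its fire year from a 12-weight distribution (ordered July–June); a
  configurable fraction burns a second time in a later month to exercise
  the not-recounted rule.
* **Seeding**: a single top-level seed deterministically derives
  per-generator substreams; all generators are bit-reproducible, and the
  RNG state of the calling session is restored afterwards.

What the generator does **not** emulate: fire spread and spatial
contagion (fires are spatially independent), fire-size distributions,
weather autocorrelation beyond the seasonal cycle and the daily synoptic
component, spatially varying climate, and observational artefacts
(omission of low-intensity burns, changing mapping methods over a
record). Tests passing on this truth therefore demonstrate that the
*estimators and accounting* are correct, not that any real record meets
the generators' assumptions.

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations to run in a
few tens of seconds on one CPU as the package's own choice of
demonstration scale: 10⁶ initializer draws, 100 × 100 × 90-year histories
(5 seeds × 3 frequencies), 10⁴ null replicates for the slope-test size,
300 replicates for the regression-multiplier recovery, and 1,000 random
states for the monotonicity suites. The analysis scripts use a 60 × 60
grid over 1930–2019 and a 6 × 6 weather grid over 1980–2019 at
0.1°. Other numerical conventions: percentile cutoffs use the default
quantile type 7 with all ties at the cutoff returned; epoch means require
complete years and error otherwise; the extrapolation guard defaults to
the observed predictor range.

## Known limitations

* No projected CRS support; grids are plain geographic.
* Raster I/O is text-based (TSV with a grid header); there is no
  GeoTIFF/NetCDF binding in this package.
* The drought factor implements the Griffiths limiting form without the
  operational cap-table refinements used by some agencies.
* FFDI values are the standard meter, not any forecast-calibrated
  product; absolute day counts from calibrated datasets will differ.
* The trend layer is OLS only; no time-series models, and the robust-SE
  option is a simple lag-1 Newey–West estimator.
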