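---
title: "Space-time weighted regression for area-level air quality and crime panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time weighted regression for area-level air quality and crime panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: the models it fits,
the assumptions they rest on, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices that matter when reproducing results.

## The scientific setting

The package implements a monthly, area-level analysis pipeline of the kind
used to relate ambient air quality to social outcomes (crime counts) across
a region's administrative units. The canonical configuration mirrors a
state-scale study: about 129 local government areas observed for 36 months
(4,644 unit-month records), with air quality measured by a station network
(about 87 monitors) rather than at the analysis units themselves. Five
stages connect raw measurements to local coefficient surfaces:

1. **AQI construction** — reduce pollutant concentrations to a daily index;
2. **interpolation** — carry station values to unit centroids;
3. **stationarity screening** — decide whether per-unit time series carry
   unit roots, which motivates modelling time explicitly;
4. **model fitting** — global OLS, cross-sectional GWR, and GTWR;
5. **diagnostics and reporting** — collinearity, residual spatial
   autocorrelation, nonstationarity of local coefficients, and seasonal
   summaries.

## Air quality index

The daily AQI at a station is the maximum over pollutants of the
concentration relative to its regulatory standard, scaled to 100:

$$\mathrm{AQI} = \max_k \left( \frac{p_k}{ps_k} \times 100 \right)$$

The standards table shipped with the package (`nsw_standards()`) holds the
New South Wales values: CO 9.0 ppm (8-hour), NO2 0.12 ppm (1-hour), ozone
0.10 ppm (1-hour) and 0.08 ppm (4-hour), SO2 0.20 ppm (1-hour), and PM10
50 and PM2.5 25 micrograms per cubic metre (24-hour). Concentrations are
assumed to arrive already averaged over each pollutant's own period and in
the standard's units; unit conversion (e.g. pphm to ppm) is input
preparation, not this package's concern. An index of 100 therefore means
"some pollutant exactly at standard". Status bands follow the NSW
reporting scheme (0-33 Very good up to 200+ Hazardous), with half-open
intervals at band midpoints for non-integer values.

Two conventions required a decision:

* **Monthly aggregation.** Daily indices are averaged (arithmetic mean)
  into station-months. The maximum and the median were considered;
  the mean is consistent with reported monthly AQI summaries in this kind
  of study and is the least surprising default. Months with no valid days
  inside a station's observed span are kept as missing rows rather than
  silently dropped.
* **Missing pollutants** on a day are skipped; the maximum runs over the
  pollutants present. A day with no valid observation at all is dropped
  before aggregation.

## Station-to-unit interpolation

Two interpolators are implemented and compared by leave-one-out
cross-validation (MAPE, in percent): inverse distance weighting and
ordinary kriging with a spherical semivariogram

$$\gamma(h) = c_0 + c \left( 1.5\,\tfrac{h}{a} - 0.5\,\tfrac{h^3}{a^3} \right), \quad h < a,$$

flat at the sill beyond the range $a$. Both use the 12 nearest stations:
the source description of the neighborhood ("12 nearby stations") states a
count, not a metric radius, so it is implemented as k-nearest-neighbour
search with `k_neighbors = 12`. Predictions are made at unit centroids,
one value per unit-month, because the downstream regression consumes
unit-level covariates; raster surfaces are out of scope.

Numerical choices:

* The empirical variogram uses the Matheron estimator on 15 equal-width
  bins up to half the maximum pairwise distance, then weighted least
  squares with bin pair counts as weights. That WLS surface is multimodal
  (a short-range structure can be traded against a nugget), so the fit
  multi-starts from a small grid of nugget and range values and keeps the
  best optimum.
* The kriging system sets the diagonal of the semivariance matrix to zero,
  the exact-interpolation convention: with a zero nugget the predictor
  honours station values exactly. Duplicate station coordinates are
  averaged before solving; a still-singular system is an error.
* Per-month independence: each month is interpolated from that month's
  station values only. Space-time kriging is a non-goal; the temporal
  structure is the regression stage's job.
* Leave-one-out MAPE excludes zero-valued observations (with a message)
  since the percentage error is undefined there; it is reported per month
  and pooled.

## Unit-root screening

The augmented Dickey-Fuller regression with a constant and no trend,

$$\Delta x_t = c + \gamma x_{t-1} + \sum_{j=1}^{p} \phi_j \Delta x_{t-j} + \varepsilon_t,$$

tests the null $\gamma = 0$ (unit root). The lag order is chosen by AIC
over `0..max_lags` on a common estimation sample, and the statistic's
p-value comes from the MacKinnon (1994) response-surface approximation for
the constant-only case — the same approximation used by the standard
econometrics references, and verified in the test suite against an
independent implementation on identical input. The default `max_lags = 4`
reflects the short monthly panels this pipeline targets (36 observations
cannot support long lag structures).

A regional summary reports, per variable, the share of units whose p-value
is at or above `alpha` (the *acceptance share*): if the majority of units
fail to reject the unit root, the variable is declared regionally
nonstationary — the generalization of the narrative rule used in studies
of this design, where e.g. a 92% acceptance share reads as nonstationary
and an 11% share as stationary. The threshold (50%) is exposed.

Deterministic series make the ADF design singular (the lagged differences
of a pure sinusoid span a two-dimensional space); singular lag orders are
excluded from selection and a fully singular series is reported as
degenerate rather than tested.

## The regression models

The global model is ordinary least squares with constant coefficients.
GTWR lets every coefficient vary over space and time: at each record $i$
it solves weighted least squares

$$\hat\beta(u_i, v_i, t_i) = (X^\top W_i X)^{-1} X^\top W_i y$$

with diagonal weights built from the combined squared space-time distance

$$d^2_{ij} = (u_i - u_j)^2 + (v_i - v_j)^2 + \tau\,(t_i - t_j)^2$$

through a Gaussian kernel $w_{ij} = \exp(-d^2_{ij}/h^2)$. The ratio
$\tau = \mu/\lambda$ converts squared months into squared metres; the
spatial scale $\lambda$ is fixed at 1 so only $\tau$ is free. $\tau = 0$
removes time from the kernel and gives GWR. Cross-sectional GWR — an
independent spatial fit per month — is the comparison model.

Conventions and caveats:

* The kernel must decay with distance; the exponent is negative. A
  fixed (not adaptive) bandwidth is used throughout — adaptive kernels are
  out of scope.
* Time distances are integer month differences. Seasons are derived labels
  used only in reporting.
* $R^2$ is computed as $1 - RSS/TSS$ about the global response mean for
  all models, so comparisons across OLS/GWR/GTWR are like-for-like.
* The model-level AICc uses the hat-matrix trace as the effective number
  of parameters:
  $n\log(RSS/n) + n\log(2\pi) + n\,(n + \mathrm{tr}\,S)/(n - 2 - \mathrm{tr}\,S)$.
* Near-singular local systems (condition number above 1e10, e.g. at tiny
  bandwidths) fall back to a ridge term of `1e-8` times the trace of the
  local normal matrix, with a warning counting affected points.
* Leave-one-out predictions (the CV score, a sum of squared errors, not a
  mean) come from a rank-one downdate of each local system — equivalent to
  forcing the record's own weight to zero, at no extra solve cost.

### Bandwidth and scale selection

`select_bandwidth()` runs a golden-section search on $h$ over
[minimum nearest-neighbour spacing, domain diameter], with an outer grid
over $\tau$ (default logarithmic, `{0, 1e-2..1e6}` scaled by the squared
nearest-neighbour spacing per squared month). Two objectives are offered:

* **CV** (default): the leave-one-out sum of squared errors. This is the
  classical choice and what the package's model-comparison tables report.
* **AICc**: preferable when the *coefficient surfaces* are the object of
  interest. CV is known to undersmooth local regression (it optimizes
  pointwise prediction, tolerating a large hat-matrix trace), and
  undersmoothed fits have noisy local coefficients. AICc trades fit
  against the hat-matrix trace and lands at smoother surfaces. The
  package's parameter-recovery test selects by AICc for exactly this
  reason; the selection attaches its search table so the objective's
  profile over the tau grid is inspectable.

Selection is deterministic given the panel. A selected bandwidth at the
search boundary triggers a warning rather than an error: on a panel with
spatially constant coefficients the optimum legitimately sits at the upper
bound.

## Diagnostics

* **VIF**: $1/(1 - R^2_j)$ from regressing covariate $j$ on the others
  with intercept; values above 5 are flagged. A perfectly collinear column
  reports `Inf`.
* **Moran's I** on OLS residuals, computed per month (a single pooled
  statistic would mix temporal and spatial structure) with
  row-standardized 8-nearest-neighbour weights — polygon contiguity is not
  available for synthetic point layouts, and k-NN weights are the standard
  fallback. The permutation p-value is one-sided (greater); `clustered`
  means I above its expectation $-1/(n-1)$ with $p < 0.05$. The share of
  significant months summarizes the screen.
* **Nonstationarity table**: per coefficient, the interquartile range of
  the GTWR local estimates and the smallest per-month IQR of the
  cross-sectional GWR estimates are compared against twice the OLS
  standard error; a larger IQR flags the coefficient as spatially
  heterogeneous. Quartiles use linear interpolation (R type 7) — stated
  explicitly because the comparison depends on the convention. Both IQR
  columns are reported; the flag is driven by the GTWR column by default,
  with the GWR column available via `flag_on`.

## The synthetic-data generator

The generator is first-class, tested code: it produces the study design
the pipeline assumes, with known ground truth so estimation error is
measurable.

* **Layout**: `n_units` centroids and `n_stations` monitor sites uniform
  over a projected rectangular domain (default 300 x 200 km, in metres —
  geographic coordinates are out of scope).
* **AQI field**: a static Gaussian random field with exponential
  covariance (range 60 km, SD 8 index units; realized exactly by Cholesky
  factorization, which is the simplest exact method at a few hundred
  sites), plus a 12-month sinusoid (amplitude 4), plus a per-site random
  walk whose innovations are themselves spatially correlated (SD 2.5 index
  units per month), around a base level of 40. The random walk is
  per-site rather than global so that every unit carries its *own*
  unit-root series — a global walk would make all unit series identical up
  to a level shift and the stationarity screen degenerate. With these
  defaults most 36-month unit series fail to reject the unit root,
  which is the regime the pipeline is designed for, while index values
  stay in a plausible range; the amplitude/innovation balance was fixed
  once on that criterion.
* **Stations** observe the latent field exactly; interpolation error
  against truth is therefore measurable.
* **Covariates**: `aqi` is the latent field at unit centroids; any other
  named covariate is a unit-level standard normal draw held constant over
  months, emulating slowly-moving socio-economic variables (their
  month-to-month changes are negligible at this resolution). Covariates
  are independent by default; their joint distribution is a free
  parameter of the design.
* **Response**: generated directly on the log scale as
  $\sum_k \beta_k(u, v, t)\,x_k + \varepsilon$ with Gaussian noise
  (SD 0.15), matching the pipeline's log-transformed modelling scale.
  Count-level simulation (and hence excess zeros) is a non-goal.
* **Coefficient surfaces** are compositions of a constant, a linear
  gradient in normalized coordinates, and a 12-month sinusoid
  (`beta_surface()`), which covers the constant / linear / seasonal cases
  and their sums.

What passing tests on this generator do *not* show: robustness to
count-valued responses with many zeros, to irregular real geographies and
population-weighted unit sizes, to covariate measurement error, or to
station networks that are sparse precisely where the field is roughest.
Those are properties of real data the generator deliberately does not
emulate.

## Problem sizes and runtime choices

The test suite runs its heavier experiments at the canonical study size
(129 units, 36 months) where the property demands it — parameter recovery
and the GTWR-vs-GWR cross-validation comparison — with bandwidth searched
on a reduced grid (four values of tau, 5% golden-section tolerance), and
at smaller sizes elsewhere. Monte-Carlo calibrations use 200-500
replicates. These sizes are the package's choice of a thorough-but-quick
default experiment; all grids and replicate counts are plain function
arguments, and nothing in the implementation depends on them.

## Known limitations

* The GTWR solver is dense: each record's local system sees all n
  records. At the canonical size a full fit is seconds; at tens of
  thousands of records a truncated-neighbourhood or compiled
  implementation would be needed.
* Log-scale Gaussian modelling of crime counts; no local Poisson
  likelihood, no mixed (semiparametric) GWR, no spatial lag/error
  econometrics.
* Isotropic variograms and kernels; no anisotropy, no co-kriging.
* The pipeline treats interpolated AQI as known when it enters the
  regression; interpolation uncertainty (the kriging variance is reported
  but not propagated) is not carried into coefficient inference.
* Association, not causation: the design has no instrument or
  quasi-experimental structure, and the package makes no causal claims.
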