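# gtwr

Spatio-temporal regression pipeline linking an air-quality index (AQI) to
area-level outcomes such as monthly crime counts. The package is aimed at
analysts working with areal panels — administrative units observed monthly
— whose key covariate (air quality) is measured at a sparse station
network, and whose relationships of interest vary over both space and
time.

It implements, end to end:

* **AQI construction** — daily index as the maximum pollutant sub-index
  `max_k (p_k / ps_k) x 100` against the New South Wales regulatory
  standards, with status bands and monthly aggregation;
* **interpolation** — inverse distance weighting and ordinary kriging with
  a spherical semivariogram (12 nearest stations), compared by
  leave-one-out MAPE;
* **stationarity screening** — per-unit augmented Dickey–Fuller tests
  (constant, no trend, AIC lag selection, MacKinnon p-values) summarized
  into a regional verdict;
* **models** — global OLS, cross-sectional GWR, and geographically and
  temporally weighted regression (GTWR): at every record *i*,

  β̂(uᵢ, vᵢ, tᵢ) = (XᵀWᵢX)⁻¹ XᵀWᵢy,  with Gaussian weights
  wᵢⱼ = exp(−d²ᵢⱼ/h²) on the combined distance
  d²ᵢⱼ = (uᵢ−uⱼ)² + (vᵢ−vⱼ)² + τ(tᵢ−tⱼ)²,

  with bandwidth `h` and space–time scale ratio `τ` selected by
  cross-validation or corrected AIC;
* **diagnostics** — VIF, per-month Moran's I on OLS residuals with a
  permutation test, and the local-coefficient IQR vs twice-OLS-SE
  nonstationarity table;
* **a seeded synthetic-data generator** with known coefficient surfaces,
  so estimation error is measurable against ground truth.

See `vignettes/gtwr-methods.Rmd` for the models, assumptions, parameter
defaults and numerical choices.

## Worked example

A daily AQI from pollutant concentrations:

```r
library(gtwr)
compute_daily_aqi(c(PM2.5 = 20, PM10 = 30, O3_1h = 0.05))
#> AQI 80.0 (Fair), dominant pollutant PM2.5
```

PM2.5 at 20 µg/m³ is 80% of its 25 µg/m³ standard — the largest of the
three sub-indices (PM10: 60, O₃ 1-hour: 50) — so the day scores 80,
"Fair", dominated by PM2.5.

The full pipeline on a synthetic study of the canonical size (129 units ×
36 months, 87 stations; about a minute on one CPU):

```r
cfg <- pipeline_config(
  synthetic = synthetic_config(),          # 129 x 36, 87 stations
  gtwr_tau_grid = c(0, 1e8, 1e9, 1e10),    # tau candidates, m^2/month^2
  gtwr_tol = 2e4,                          # bandwidth search tolerance, m
  out_dir = "run", seed = 42)
res <- run_pipeline(cfg)

res$adf
#>   variable min_stat median_stat   max_stat accept_rate       verdict
#> 1 response -6.36982   -3.787754 -1.9116424    13.95349    stationary
#> 2      aqi -5.57340   -2.645900 -0.2791375    61.24031 nonstationary

attr(res$interpolation$mape, "pooled")
#>      idw  kriging
#> 22.95946 19.87186

res$fits$comparison[, c("model", "r_squared", "cv_score", "h", "tau")]
#>             model r_squared cv_score         h   tau
#> 1             OLS 0.4624699       NA        NA    NA
#> 2 GWR (per month) 0.6668696 152.4396 345538.23    NA
#> 3            GTWR 0.7582281 146.0213  23622.78 1e+08
```

Reading the output: most units' AQI series fail to reject a unit root
(acceptance share 61%), so the variable screens as regionally
nonstationary and a time-aware model is warranted; kriging beats IDW on
leave-one-out MAPE (19.9% vs 23.0%), so the kriged values feed the
regression; and GTWR attains the best fit (R² 0.76 vs 0.46 for OLS) with
a lower cross-validation score than independent per-month GWR fits. The
run directory also holds the per-record local coefficients, the
nonstationarity table, per-month Moran's I, and seasonal coefficient
summaries (mean/min/max and share positive per variable, season and
year).

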