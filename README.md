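# bagwormRH

Forecasting oil-palm bagworm (*Metisa plana*) outbreaks from
satellite-derived relative humidity.

Bagworms are leaf-defoliating caterpillars and one of the most damaging
pests of oil-palm plantations in Southeast Asia; even moderate defoliation
measurably reduces fruit-bunch yield. Their population dynamics respond to
atmospheric humidity — egg hatchability, larval survival and fungal
epizootics are all humidity-driven — but with a delay of one to several
weeks. `bagwormRH` implements, as a tested and reusable R pipeline, an
analysis chain that predicts block-level bagworm census counts from
relative humidity (RH) retrieved from satellite near-infrared (NIR)
imagery, for plantation agronomists and quantitative ecologists who want to
build or stress-test such early-warning models.

## What the package computes

**RH retrieval** (`derive_rh()`). From five NIR apparent-reflectance bands
(window bands at 0.865 and 1.24 um, absorption bands at 0.905, 0.936,
0.940 um), a surface air temperature grid Ta (degC) and elevation H (m):

- observed transmittance by channel ratio, e.g.
  `Tobs17 = rho*(0.905)/rho*(0.865)`,
  `Tobs19 = rho*(0.940)/[0.8 rho*(0.865) + 0.2 rho*(1.24)]`;
- per-band precipitable water `PW = ((alpha - Tobs)/beta)^2` with
  Malaysian-calibration coefficients (three switchable algebraic variants,
  see the vignette), fused as `PW = 0.36 PW17 + 0.24 PW18 + 0.40 PW19`;
- specific humidity `Q = 0.001(-0.0762 PW^2 + 1.753 PW + 12.405)`,
  air pressure `Pa = 1013.3 - 0.1038 H` (hPa),
  vapour pressure `e = Q Pa / 0.622`,
  saturation vapour pressure `es = 611 exp(17.27 Ta / (237.3 + Ta))` (Pa,
  converted to hPa), and finally `RH = 100 e / es`, clamped to [0, 100].

**Zonal lag assembly** (`resample_nearest()`, `area_weighted_mean()`,
`build_block_series()`, `assemble_lagged()`). RH rasters are resampled
(nearest neighbour, 1 km to 250 m), averaged over each management block by
exact pixel-polygon intersection areas, and paired with each biweekly
census count through six lagged predictors `rh_T1 ... rh_T6` — the mean RH
in an 8-day window ending 7k days before the census date.

**Models** (`fit_regression()`, `stepwise_select()`, `qp_mlp()`).
Pearson screening per census cycle; single/multiple linear and polynomial
regressions `y = a + sum beta_k X_k (+ gamma_k X_k^2)` with SAS-style
partial-F stepwise selection; and a single-hidden-layer perceptron `k-x-1`
with logistic activations trained by full-batch quickprop, with [-1, 1]
input scaling, a 60/20/20 train/test/validation split, fitness-driven
hidden-size search and forward stepwise feature selection.

**Evaluation** (`absolute_error()`, `minmax_accuracy()`,
`adjusted_r2_actual_vs_predicted()`, `evaluate_model()`): mean absolute
error, min-max accuracy `mean[min(a,p)/max(a,p)] x 100`, and the adjusted
R^2 between actual and predicted counts.

**Synthetic estate** (`estate_layout()`, `generate_scene()`,
`simulate_block_rh()`, `generate_census()`). Because the original census
and imagery are not public, the package ships a generator for a 2000-ha,
26-block estate: reflectance scenes constructed by inverting the retrieval
chain around a known true RH field, and census series with a configurable
(nonlinear, lagged) count-vs-RH response in the observed 0-32
larvae-per-frond range. Every stage is therefore testable against planted
truth.

`run_pipeline()` executes the whole chain end to end from one seeded
configuration and writes the comparison tables.

## Worked example

```r
library(bagwormRH)
lay <- estate_layout()

# a scene with known precipitable water; the retrieval recovers its RH field
sc <- generate_scene(lay, true_pw = 3, true_ta_celsius = 30,
                     elevation_m = 50, seed = 1)
derive_rh(sc)
#> <rh_raster> (clamped to [0,100]) pw_variant = as_printed_grouped
#> <rh_grid> 6 x 7 cells, 1000 m pixels
#>   extent: x [0, 7000], y [0, 6000]
#>   values: [64.8317, 64.8317]

# two years of daily block RH, a census driven nonlinearly by the T1-T3 lags
dates <- seq(as.Date("2014-01-10"), by = "1 day", length.out = 730)
series <- simulate_block_rh(lay, dates, seed = 1)
census <- generate_census(lay, series, response_spec(seed = 101),
                          epoch = as.Date("2014-03-01"))
class(series) <- c("block_rh_series", "data.frame")
ds <- clean_dataset(assemble_lagged(series, census))
sp <- split_dataset(ds, seed = 1)

fit_regression(sp$train, lags = 1:3, degree = 1)
#> <rh_reg> count = 19.78 -0.1659(T1) +0.2444(T2) +0.03318(T3)
#>   n = 734, adjusted R^2 = 0.0119

ann <- qp_mlp(sp$train, c("rh_T1", "rh_T2", "rh_T3"), hidden = 6,
              validation = sp$validation, config = train_config(seed = 1))
evaluate_model(ann, sp)
#> <eval_report> (qp_mlp, p = 1, accuracy mode = elementwise)
#>       split   n absolute_error minmax_accuracy_percent adjusted_r2
#>       train 734          1.404                   94.04      0.9238
#>        test 244          1.576                   93.56      0.9061
#>  validation 244          1.356                   94.36      0.9305
```

The linear regression is nearly blind to the peaked humidity response
(adjusted R^2 = 0.01) while the quickprop network explains most of the
held-out variance (0.91) — the qualitative regression-vs-network contrast
this kind of analysis reports, reproduced here on data whose generating
response is known.

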