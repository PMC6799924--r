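---
title: "Methods: humidity-driven bagworm forecasting with bagwormRH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: humidity-driven bagworm forecasting with bagwormRH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagwormRH)
```

`bagwormRH` models the delayed response of oil-palm bagworm (*Metisa
plana*) censuses to satellite-derived relative humidity (RH). This
vignette is the package's own account of the science: the retrieval chain
and its assumptions, the lag construction, the two model families and how
they are compared, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the underlying method
left room.

## 1. The RH retrieval chain

The retrieval converts five near-infrared apparent reflectances, a surface
air temperature grid `Ta` (degC) and an elevation grid `H` (m) into an RH
raster in five algebraic steps:

1. **Observed transmittance** by channel ratio. Water vapour absorbs at
   0.905, 0.936 and 0.940 um but not in the window bands at 0.865 and
   1.24 um, so the ratio of an absorption band to the window signal
   estimates two-way atmospheric transmittance:
   `Tobs17 = rho(905)/rho(865)`, `Tobs18 = rho(936)/rho(865)`,
   `Tobs19 = rho(940)/(0.8 rho(865) + 0.2 rho(1240))`.
2. **Precipitable water** per band, `PW = ((alpha - Tobs)/beta)^2` (cm),
   with Malaysian-calibration coefficients
   `(alpha, beta) = (0.025, 0.30), (0.056, 0.60), (0.120, 0.651)`,
   fused across bands with weights `(0.36, 0.24, 0.40)`.
3. **Specific humidity** `Q = 0.001(-0.0762 PW^2 + 1.753 PW + 12.405)`
   (kg/kg) and **air pressure** `Pa = 1013.3 - 0.1038 H` (hPa).
4. **Vapour pressures**: actual `e = Q Pa / 0.622` (hPa) and saturation
   `es = 611 exp(17.27 Ta / (237.3 + Ta))` (Pa).
5. **RH** `= 100 e / es`, clamped into [0, 100] (raw values retained).

Assumptions: cloud-free, radiometrically calibrated apparent reflectances
on a shared projected grid; a uniform calibration of the transmittance
coefficients across the scene; elevation static in time. The package does
not reproject, calibrate DNs, or mask clouds — missing pixels propagate as
`NaN` through every stage.

### Numerical decisions in the chain

- **Unit harmonization.** Step 4 yields `es` in pascals (611 Pa at 0 degC)
  but `e` in hPa, because `Pa` from step 3 is in hPa. Taking the ratio
  naively would put RH off by a factor of 100, contradicting the 47-71%
  range the retrieval is calibrated for. `derive_rh()` therefore converts
  `es` to hPa before the ratio. `saturation_vapour_pressure()` exposes
  both units; its default (`"Pa"`) preserves the textbook constant.
- **The PW formula's grouping is ambiguous** in the source material
  (`PW=(alpha-(Tobs)/beta)^2` as printed), and the channel-ratio
  literature it descends from uses a logarithmic form. Rather than guess,
  `precipitable_water()` implements three variants —
  `as_printed_grouped` (default, `((alpha - Tobs)/beta)^2`),
  `as_printed_literal` (`(alpha - Tobs/beta)^2`) and `log_form`
  (`((alpha - ln Tobs)/beta)^2`) — and records the variant in the output
  metadata. All downstream stages are variant-agnostic, and the synthetic
  round-trip tests pass for each variant.
- **PW validity domain.** The quadratic for `Q` peaks at
  `PW ~ 11.5` cm; beyond the vertex it would make `Q` decrease with
  increasing water vapour. PW outside `[0, 11.5]` becomes `NaN` with a
  warning instead of being extrapolated.
- **Zero denominators** (a zero window-band reflectance, `es = 0`) yield
  `NaN` at that pixel, never an exception for the whole scene.

## 2. From rasters to lagged predictors

Block-level RH is the **area-weighted mean** of the raster over each
management-block polygon: the sum of (pixel-polygon intersection area x
pixel value) over the total intersected area. Intersection areas are exact
— each polygon is clipped against each candidate pixel rectangle
(Sutherland-Hodgman) and measured by the shoelace formula — rather than
approximated by centroid membership, because blocks of tens of hectares
sit on 250-m pixels where fractional coverage matters. Rasters are first
resampled from 1 km to 250 m by nearest neighbour (`resample_nearest()`),
which introduces no new values. `NaN` pixels are excluded from both sums;
a block mean is reported only when at least 50% (configurable) of the
block area has valid pixels.

Each census count is then paired with six lagged predictors. Lag `Tk`
(k = 1..6 weeks) is the mean RH in a window of `window_days` (default 8)
**ending exactly 7k days before the census date**. The source analysis
says only "k weeks prior" without anchoring the averaging window; the
end-anchored convention makes `T1` use the most recent pre-census week,
which is the natural forecasting reading, and the 8-day default mirrors
the 8-day averages its correlation tables describe. Both are
configurable. Rows missing any required lag are dropped and logged, and
`clean_dataset()` additionally removes count outliers (`|z| > 3` by
default, or 1.5-IQR fences, or none) before modelling.

## 3. The two model families

**Regressions.** Ordinary least squares of counts on selected lags
(`degree = 1`) or on lags plus their squares (`degree = 2`), via `lm()`.
Stepwise selection follows the classical partial-F forward-backward
procedure with entry/stay thresholds of 0.15 (a common statistical-package
default; the source does not state its thresholds), ties broken toward the
smaller lag. The selected term sets are data-dependent outcomes, not
assertions.

**The quickprop network.** A `k-x-1` perceptron, logistic activations on
hidden and output layers, trained full-batch. Per weight, with gradient
`S(t) = dE/dw`:

- first epoch, or a vanished previous step: plain gradient descent
  `-lr * S`;
- otherwise the secant ("quadratic") step
  `S(t) / (S(t-1) - S(t)) * step(t-1)`, replaced by the maximum-growth
  step `mu * step(t-1)` when the slope has shrunk past the factor
  `mu/(1+mu)` (exactly where the secant step would exceed that bound or
  point backwards), plus a gradient term `-lr * S` while the slope still
  points along the previous step.

This is the full classical per-weight rule. During development, a reduced
rule (secant with a magnitude cap and gradient fallback only) exhibited
the textbook failure mode — steps compounding by `mu` each epoch into
hidden-unit saturation while the error crept up — which the shrink-factor
test and the aligned-gradient term are precisely designed to prevent; the
unit tests pin each branch of the rule to hand-computed cases.

Defaults (`train_config()`): `mu = 1.75`, `learning_rate = 0.1`,
`max_epochs = 500`, `patience = 25`, `weight_decay = 0` — conventional
quickprop settings, all configurable. Training stops at `max_epochs` or
after `patience` epochs without validation improvement, and returns the
weights with minimum validation error (training error when no validation
set is supplied). Divergence (error above 1e6) aborts with a diagnostic.

**Scaling.** Features and the target are min-max scaled to [-1, 1]. The
logistic output cannot reach the scaled extremes, so internally the scaled
target is mapped onto [0.1, 0.9] of the output range (an 80% sub-range)
to keep targets away from the asymptotes; the inverse map clamps to
[-1, 1], so back-transformed predictions always lie within the training
target range. A zero-weight network outputs 0.5 in logistic space — the
midpoint of the target range — for any input.

**Splitting.** 60/20/20 train/test/validation by seeded shuffle, with
`floor` rounding on the test and validation parts and the remainder to
training; this rounding rule is the one that maps 282 rows to 170/56/56.

**Architecture and feature search.** The hidden size is chosen over
1..10 by network *fitness*, defined as `1 / (1 + validation mean absolute
error)`; the source never defines its fitness value, so this inverse-error
form is an explicit package decision recorded in the outputs. Ties go to
the smaller network. Feature masks are chosen by greedy forward selection
on the same fitness, stopping when no addition improves it.

**Evaluation.** Mean absolute error; min-max accuracy; and the adjusted
R^2 between actual and predicted values (`1 - (1-R^2)(n-1)/(n-p-1)` from
regressing actual on predicted). The min-max accuracy formula
(elementwise mean of min/max ratios) and its prose description (ratio of
pooled means) disagree in the source; both are implemented
(`mode = "elementwise"` default, `"pooled"` alternative) and the mode is
recorded in every report. Rows where both values are zero count as
perfect agreement; rows where exactly one is zero are excluded with a
warning, the source being silent on both. For network predictions the
adjustment uses `p = 1` (the single regression slope); for regressions,
the number of fitted terms.

## 4. What the synthetic estate emulates

No census or imagery from the original study area is public, so the
generator creates the full input stack with known truth:

- **Layout**: a 2000-ha estate of 26 rectangular blocks in two divisions
  (10 of 80 ha, 16 of 75 ha), offset inside a 7 x 6 km, 1-km-pixel grid so
  block edges straddle pixels and the zonal weights are genuinely
  fractional.
- **Scenes** (`generate_scene()`): window-band reflectances jittered
  around 0.45/0.40, absorption-band reflectances solved from the
  transmittance that makes the forward chain reproduce a prescribed
  true-PW field exactly. Each variant is inverted on the root that keeps
  reflectances positive and within (0, 1.5] (the positive `Tobs` branch
  for the printed forms, the decaying exponential branch for the log
  form). `pw_for_rh()` closes the loop from a target RH to the PW that
  produces it, inverting the `Q` quadratic on its monotone branch.
- **Weather** (`simulate_block_rh()`, and the pipeline's field
  simulator): RH around 59% with a seasonal sine (amplitude 4), a shared
  AR(1) day-to-day component (phi 0.6, innovation SD 4), block offsets and
  pixel noise, clamped to the observed 47-71% range; air temperature
  anti-correlates with daily humidity, which also keeps target fields
  inside the invertible PW domain.
- **Census** (`generate_census()`, `response_spec()`): biweekly counts on
  a fixed 14-day calendar (the source gives no dates; 24 cycles/year for
  2 years by default), with counts
  `clamp(shape(z) + noise, 0, 32)` where `z` is the lag-weighted RH.
  The default response is a peaked quadratic centred at 59% RH with
  half-width 8 points and peak 32, on weights
  `T1..T3 = 0.45/0.35/0.20`, with noise SD 2 counts: a humid-optimum
  response concentrated in the recent lags. The defaults were chosen so
  that (i) counts span the observed 0-32 range over the observed RH
  range, and (ii) the signal is nonlinear in every individual lag with
  substantial cross-lag structure — the weekly windows are nearly
  uncorrelated under the AR component, so the squared weighted sum
  contains cross-products that an additive polynomial regression cannot
  represent but the perceptron can, which is the mechanism this class of
  analysis attributes its network-over-regression advantage to. Shapes
  `linear` and `saturating` (logistic) are available alternatives.
- **Palm level** (`generate_palm_level_census()`): the 25 per-palm counts
  behind one block average are Poisson draws with the block mean as
  intensity; the source does not model palm-level dispersion, and the
  Poisson choice keeps counts non-negative integers whose average obeys
  the block-averaging convention.

The generator does **not** emulate cloud-induced gaps, spatial contagion
between blocks, instar-stage dynamics, pesticide interventions, or sensor
noise in the reflectances. Passing tests therefore demonstrate that the
pipeline's arithmetic, plumbing and estimators are correct and that the
qualitative network-vs-regression contrast emerges under a known nonlinear
lagged response — not that the fitted models transfer to any real estate.

## 5. Problem sizes and determinism

The test suite and the end-to-end comparison run at the estate's native
scale: 26 blocks x 48 biweekly cycles (1248 rows before cleaning), ~730
daily RH values per block, 6 x 7-cell scenes at 1 km resampled to 250 m.
The network comparison trains 3-6-1 networks for up to 300 epochs across
five seeds; the full `run_pipeline()` demonstration fits all nine
predictor configurations (six single lags, T1-T3, T4-T6, and automatic
selection) with a 1..10 hidden-size search in well under a minute on one
core. Every random draw — weather, noise, splits, weight initialization —
flows through one seed per generator (the pipeline derives per-stage child
seeds from a single root), so reruns are bit-identical; file outputs
(lagged dataset CSV with a JSON sidecar, model JSONs, comparison CSVs, a
run manifest) carry enough metadata to reproduce a run exactly.

## 6. Known limitations

- The retrieval is only as good as its calibration; the coefficient
  registry ships one (Malaysian) calibration and the package provides no
  means to refit it.
- Lagged predictors built from overlapping windows of an autocorrelated
  series are themselves correlated across rows; neither the regressions
  nor the network accounts for residual autocorrelation, mirroring the
  source analysis. Reported adjusted R^2 values on the synthetic data are
  accordingly optimistic relative to a blocked or temporal cross-validation.
- The min-max accuracy is undefined for negative values; regression
  predictions are clamped at zero for that metric only.
- Quickprop is a heuristic second-order method: it is fast on these
  problem sizes but, like all its implementations, sensitive to
  `learning_rate` on badly scaled data. The [-1, 1] scaling keeps the
  defaults serviceable.
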