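# yieldkrige

Hybrid village-to-pixel crop yield disaggregation with residual kriging.

## The problem

Crop yield statistics in smallholder regions are reported at administrative
support — a single average per village or block — while agronomic decisions,
insurance and household-level assessment need yields at field or pixel scale.
`yieldkrige` is a toolkit for **area-to-point yield disaggregation**: it learns
the relationship between village mean yields and zonally aggregated satellite,
weather and soil covariates, applies that model at pixel support, and then
corrects the systematic regional bias the covariate model cannot see by
geostatistically interpolating its village-level residuals. It is written for
agricultural remote-sensing researchers and methodologists who want a fully
inspectable, dependency-light R implementation with a synthetic-landscape
simulator so every stage can be validated against known pixel truth.

## The method

**1. Downscaling model.** Village samples pair observed yields
*y<sub>i</sub>* (quintal/ha) with masked zonal means of covariate layers.
Model families, one fitting front-end (`fit_yield_model()`):

- linear, ridge (exact L2-penalized normal equations), lasso — the screening
  baselines;
- random forest, two gradient-boosting configurations (100 trees, η = 0.1,
  seed 42);
- a two-branch recurrent network: satellite-band sequences (T₁ = 3 months ×
  F₁ = 7 bands) and weather sequences (T₂ = 5 × F₂ = 6) each pass through
  their own 32-unit LSTM or GRU cell and a 16-unit ReLU dense layer; the two
  16-vectors are concatenated with the static input (F₃ = 1) into a 33-wide
  merge, then a 128–64–32 ReLU head (dropout 0.1) and a Softplus output
  ŷ = log(1 + e<sup>u</sup>) that keeps yields non-negative. The LSTM variant
  has 25,889 trainable parameters and the GRU (double-bias formulation)
  23,553; `count_trainable_parameters()` reproduces both from closed form.
  Training: Adam on MSE, MAE monitored, batch 32, ≤ 500 epochs, early
  stopping with patience 25 and best-weight restoration.

**2. Residual kriging.** Residuals e<sub>i</sub> = y<sub>i</sub> − ŷ<sub>i</sub>
at village centroids s<sub>i</sub> are summarized by the empirical
semivariogram

γ̂(h) = 1/(2N(h)) Σ [e(sᵢ) − e(sᵢ+h)]²,

fitted with pair-count-weighted least squares under four candidate models
(linear, spherical, gaussian, exponential). The model with the lowest
leave-one-out ordinary-kriging RMSE is selected (`select_variogram_cv()`),
residuals are kriged to every masked pixel with the unbiasedness constraint
Σλᵢ = 1 enforced by a Lagrange multiplier, and the kriged surface is added
back: y\*(s) = ŷ(s) + e<sub>krig</sub>(s).

**3. Evaluation.** R², adjusted R², RMSE, MAE, MAPE; Friedman rank test
χ²_F = 12N/(k(k+1)) (ΣR̄²ⱼ − k(k+1)²/4) with Nemenyi critical difference
CD = q<sub>α</sub>√(k(k+1)/6N); Moran's I under binary symmetrized kNN-8
weights with permutation inference — the diagnostic that decides whether
residuals are spatially structured enough for kriging to help.

A synthetic-scene generator (`generate_scene()`) produces landscapes with a
known pixel-level truth: smooth latent fertility/moisture fields driving the
covariates, weather constant over coarse blocks (mirroring reanalysis-grade
data where many villages share identical weather values), Voronoi village
polygons, an optional smooth regional bias invisible to every covariate, and
village means as the only observed yield.

## Worked example

```r
library(yieldkrige)

scene <- generate_scene(scene_config(trend = c(2, 2), seed = 42))
fit <- hybrid_downscale(scene, method = "gru", seed = 42)
print(fit)
```

```
hybrid_downscale: gru on 'band-weather' + residual kriging (spherical variogram)
  residual Moran's I 0.653 (p = 0.001) -> -0.102 (p = 0.971) after correction
Village-level performance:
      method     r2  adj_r2   rmse    mae  mape
 uncorrected 0.6558 -1.5387 5.0307 4.2373 6.606
   corrected 0.9896  0.9235 0.8732 0.6508 1.042
Block-level performance:
      method   rmse    mae   mape
 uncorrected 4.2937 4.1141 6.3799
   corrected 0.1263 0.1115 0.1768
```

The scene injects a planar bias of 2 quintal/ha per km that no covariate
carries, so the GRU alone leaves strongly clustered residuals (Moran's I
0.653, permutation p at the 0.001 floor). Kriging the village residuals and
adding the surface back removes the clustering (I ≈ −0.10, p ≈ 0.97,
indistinguishable from spatial randomness) and cuts village-level RMSE from
5.03 to 0.87 quintal/ha — the hybrid pattern the package exists to deliver.
`summary(fit)` additionally prints the per-model leave-one-out CV RMSEs
behind the variogram selection.

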