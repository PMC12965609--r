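---
title: "Hybrid yield downscaling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid yield downscaling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`yieldkrige` turns administrative crop-yield statistics (one mean per
village, in quintal/ha) into pixel-scale yield surfaces. This vignette is the
package's own account of the method: what is modelled, what is assumed, which
knobs matter, and where the design was genuinely open.

## The two-stage model

**Stage 1 — covariate-driven downscaling.** Village samples pair the observed
yield $y_i$ with masked zonal means of a covariate stack: monthly
satellite-band composites (3 time steps x 7 optical/radar features), monthly
weather surfaces (5 x 6), and static soil layers. Any of the model families in
`fit_yield_model()` — linear/ridge/lasso regression, random forest, two
gradient-boosting configurations, or the two-branch recurrent network —
learns $y_i \approx f(\bar{x}_i)$ at village support and is then evaluated at
pixel support, $\hat y(s) = f(x(s))$. This deliberately commits the standard
area-to-point approximation: a model trained on areal means is applied to
point (pixel) covariates. It is unbiased when $f$ is linear and the mask is
dense; for nonlinear $f$ the aggregation bias is part of what stage 2 absorbs.

The recurrent downscaler mirrors the temporal structure of the inputs: each
sequence branch (bands, weather) runs through its own 32-unit LSTM or GRU
cell, the final hidden state passes a 16-unit ReLU layer, and the two branch
codes are concatenated with the static features into a 33-wide vector feeding
a 128-64-32 ReLU head and a Softplus output that enforces $\hat y \ge 0$.
The closed-form parameter counts (25,889 for LSTM, 23,553 for GRU with the
double-bias "reset-after" formulation; `count_trainable_parameters()`) are
pinned by tests, so any refactor of the layer definitions that changes the
effective architecture is caught immediately.

**Stage 2 — geostatistical residual correction.** Whatever stage 1 misses
that is spatially smooth — regional management gradients, unobserved soil or
irrigation structure, weather too coarse to differ between villages — shows
up as spatially autocorrelated village residuals
$e_i = y_i - \hat y_i$. The package models them with an empirical
semivariogram, selects among linear/spherical/gaussian/exponential models by
leave-one-out ordinary-kriging RMSE, kriges the residuals to every masked
pixel (weights summing to one via a Lagrange multiplier), and adds the
surface back: $y^*(s) = \hat y(s) + e_{krig}(s)$. Moran's I with symmetrized
binary kNN-8 weights, with permutation inference, is the diagnostic for
whether stage 2 has anything to correct — and, recomputed after correction,
for whether it worked.

Key assumptions: one shared projected CRS in metres (the package never
reprojects); residual second-order stationarity and isotropy; villages
represented by their centroids for kriging (the centroid surrogate for true
area-to-point kriging); no detrending of residuals before kriging.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `split_fraction` | 0.8 | — | 80:20 train/validation split; train count is `floor(0.8 n)` |
| recurrent units / branch | 32 | — | fixed branch width; with dense 16 gives the 33-wide merge |
| dropout | 0.1 | rate | after each head layer; regularizes the small-sample fit |
| batch / epochs / patience | 32 / 500 / 25 | — | Adam on MSE, early stop on validation loss, best weights restored |
| trees / learning rate | 100 / 0.1 | — | tree ensembles, seed 42 |
| `n_lags` | 15 | bins | empirical semivariogram resolution |
| `max_dist` | half max pair distance | m | standard cutoff; beyond it bins are noise-dominated |
| kNN `k` | 8 | neighbours | Moran weight matrix |
| permutations | 999 | draws | p-value floor 1/1000 |

Early stopping monitors validation loss by default; the monitored MAE is also
recorded per epoch and can be selected (`train_config(monitor = "val_mae")`)
— both conventions are defensible and the choice is exposed rather than
hidden. Input standardization is per time-feature column, with statistics
estimated on the training split only and stored on the model; ridge and lasso
z-score features the same way. Dropout placement (after each head dense
layer) is recorded in the specification object so it is auditable.

## What the synthetic landscape emulates — and what it does not

`generate_scene()` builds a 100 x 100 grid at 100 m (10 km x 10 km) with 60
Voronoi villages in a 2 x 2 block grid. Yield truth is
`intercept + 4*fertility + 2*moisture + structured residual (+ optional
planar trend)`, with the two drivers simulated as smooth exponential Gaussian
random fields (circulant embedding on a doubled torus; negative embedding
eigenvalues are clipped, a negligible perturbation at these sizes) and the
structured residual an exponential field of sill 4 (sd 2 quintal/ha) that no
covariate carries. Defaults: intercept 45 quintal/ha (winter-wheat scale),
observation noise sd 0.5 quintal/ha on village means, Bernoulli crop mask at
85% coverage, weather piecewise-constant on 25-pixel (2.5 km) blocks so that
many villages share identical weather values, as reanalysis-grade forcing
does in the real data situation this emulates. Optical bands load on
fertility with NIR positive and Red negative (so NDVI is informative), radar
on moisture, soils weakly on fertility.

The generator deliberately omits: radiative-transfer or phenological realism,
cloud artifacts, anisotropy, non-stationary variograms, reporting bias in
yield statistics, and crop-mask error. Passing tests therefore demonstrate
the *statistical machinery* — recovery of known spatial structure,
conservation identities, the benefit of residual kriging under structured
bias — not agronomic validity on any particular real landscape.

The end-to-end experiment in the test suite injects a planar bias of 2
quintal/ha per km (about a 20 quintal/ha sweep over the scene, comparable to
the between-village spread) that is invisible to every covariate, trains the
GRU downscaler, and requires residual Moran's I to be significant before
correction and village-aggregated RMSE to drop by at least 20% after it,
across seeded replicates. Problem sizes throughout the suite (40-100 pixel
grids, 25-80 villages, 15-500 epochs) are chosen so the whole suite exercises
every stage, including recurrent training, at desk scale.

## Numerical choices

- **Semivariogram definition.** $\gamma(0) = 0$ by definition; the nugget is
  the limit from the right. The kriging matrix uses a zero diagonal while the
  prediction right-hand side evaluates `nugget + structure(h)` (equal to the
  nugget at $h = 0$), so interpolation is exact at data points iff the nugget
  is zero and smooths otherwise.
- **Range conventions.** Spherical reaches its sill exactly at `range`;
  exponential and gaussian use correlation-length parameterizations
  ($1 - e^{-h/a}$, $1 - e^{-(h/a)^2}$) with practical ranges ~$3a$ and
  ~$\sqrt{3}a$. The linear model is `nugget + slope*h` and is excluded from
  field simulation (no finite variance) but allowed in kriging.
- **Variogram fitting.** Pair-count-weighted least squares; bounded
  quasi-Newton from several deterministic starts (sill at the empirical
  plateau, range at 1/3, 1 and 1/10 of the maximum lag); non-convergence
  falls back to the linear model with a warning. Fitting with Cressie-style
  iteratively reweighted schemes was evaluated and performed worse for model
  discrimination, so the simpler estimator stays.
- **Selection tie-break.** Minimum LOO-CV RMSE wins; exact ties resolve in
  the order linear < spherical < gaussian < exponential (simplest first).
  A caution established by the package's own seeded experiments: with ~100
  points, spherical and exponential semivariograms share near-origin
  behaviour and a gaussian-plus-nugget model mimics exponential kriging
  weights closely, so CV differences sit in the third decimal and the *type*
  recovered is unstable even when the kriged surface itself is accurate.
  Selected types should be read as interchangeable near-optima, not as
  inference about the true covariance family.
- **Ridge is exact.** The L2 objective has a closed-form minimizer, so ridge
  solves the normal equations directly (unpenalized intercept, z-scored
  features, 10-fold CV over a log-spaced grid when no penalty is given);
  coordinate descent could not reproduce the $\lambda \to 0$ OLS limit to
  contract tolerance. Lasso keeps coordinate descent (glmnet), its canonical
  algorithm.
- **Degenerate inputs** are errors or flags, never silent repairs: villages
  with zero eligible pixels are flagged; an all-zero NDVI unit gets no
  uniform fallback; constant fields make Moran's I error; duplicate kriging
  locations are rejected; NaN training loss aborts with a diagnostic.
- **Determinism.** Every stochastic step (field simulation, mask, split,
  weight init, shuffling, dropout, permutations, tree fits) is governed by an
  explicit seed; identical seeds give byte-identical pipeline reports.

## Open design decisions

- **Pixel inclusion rule** for zonal statistics is pixel-centre-in-polygon
  with half-open cells — deterministic and standard; the alternative
  (area-weighted coverage) costs far more and changes village means
  negligibly at 100 m resolution.
- **The split is simple random**, not stratified by block; stratification is
  a reasonable variant but plain random matches the stated sample counts and
  keeps one seed the only control.
- **Production vs yield in weight-based allocation.** The NDVI weight-based
  allocator distributes reported *production* (quintal); mass conservation
  per unit is asserted to float tolerance. The percentile-based scaler is
  implemented exactly as published — a pure slope with no intercept — even
  though common variants anchor the output at the minimum yield; NDVI of zero
  therefore maps to yield zero, which is documented rather than "fixed".
- **Yield bounds for the percentile scaler** default to the max/min observed
  village yields within the district being disaggregated.
- **ATPK surrogate.** True area-to-point kriging would integrate the
  covariance over polygon supports and enforce mass coherence; the package
  kriges from centroids instead, which reproduces constants, is exact at
  centroids with zero nugget, and serves the benchmark role.
- **GB vs XGB.** Both gradient-boosting baselines run on the same boosting
  engine with different configurations (depth-3 trees, full subsampling,
  no L2 term vs regularized defaults), reflecting a classical versus a
  regularized boosting setup under identical tree count and learning rate.

## Known limitations

Kriging is global (all villages in one system), fine up to ~1,000 villages;
beyond that a local neighbourhood would be needed. No kriging-variance
(uncertainty) surfaces. Isotropic variograms only. The recurrent models are
trained on CPU-scale sample counts; with only tens of training villages their
advantage over ensembles is not guaranteed — which is precisely why the
residual-kriging stage, not the network, carries the bias correction. MAPE
excludes zero-valued observations (with a count) and block-level R² is
deliberately not reported, since a handful of blocks cannot support a stable
coefficient of determination.
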