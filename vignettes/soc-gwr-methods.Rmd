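---
title: "Methods: soil organic carbon stocks by geographically weighted regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil organic carbon stocks by geographically weighted regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socgwr)
```

## The problem and the model

Soil organic carbon (SOC) stocks to 1 m depth vary over continental
extents in ways no single global regression captures: the same predictor
(say, mean annual temperature) can raise stocks in a subtropical wetland
and lower them in a temperate prairie. `socgwr` implements the standard
digital-soil-mapping pipeline for this situation:

1. **Stocks from profiles.** Each pedon contributes a fixed-depth
   0--100 cm stock, `sum((soc_pct/100) * bulk_density * thickness_cm * 100)`
   in Mg/ha, with layers straddling 100 cm counted pro-rata. No
   coarse-fragment correction is applied; concentrations are treated as
   fine-earth basis and bulk density is taken as given per layer
   (pedotransfer imputation is out of scope; layers with missing bulk
   density are dropped on read, with a count).
2. **Outliers, then transform.** Stocks outside `Q1 - 1.5 IQR` to
   `Q3 + 1.5 IQR` *within their ecoregion* are removed in a single pass
   (fences are not recomputed after removal, so the filter is
   deliberately not idempotent). Filtering precedes everything else and
   acts on the raw Mg/ha scale. The surviving training stocks then get a
   Box-Cox transform, `z = (y^lambda - 1)/lambda` (`log y` at
   `lambda = 0`), with the exponent maximizing the profile log-likelihood
   `-(n/2) log(RSS(lambda)/n) + (lambda - 1) sum(log y)` over a coarse
   grid on `[-2, 2]` (step 0.01) refined by golden section to 1e-4. The
   transform is fitted on the training partition only and reused
   everywhere else, to avoid leakage.
3. **Screening.** Pearson correlation pruning among the continuous
   predictors (`|r| > 0.70`, computed once; the lower-priority member of a
   still-intact pair is dropped, walking pairs in decreasing `|r|`);
   indicator (0/1) layers are exempt, since a product-moment correlation
   between dummies is not the collinearity being screened. A simple
   random 75/25 split precedes model selection. Best-subset multiple
   regression then maximizes adjusted R^2 subject to an overall F-test
   and per-coefficient partial t-tests at `alpha = 0.05`; with more than
   15 surviving predictors, forward stepwise proposes one candidate per
   size instead of the 2^p enumeration. A Pearson-vs-Spearman screen per
   predictor is logged as a nonlinearity diagnostic; no transformation is
   applied automatically.
4. **GWR.** At every calibration point a weighted least-squares fit
   `beta(u) = (X'W(u)X)^{-1} X'W(u) z` is solved, with bisquare kernel
   weights `(1 - (d/b)^2)^2` inside an adaptive bandwidth `b` equal to
   the distance to the k-th nearest calibration point. The neighbour
   count k is chosen by minimizing the corrected AIC,
   `AICc = 2n log(sigma) + n log(2 pi) + n (n + tr S)/(n - 2 - tr S)`,
   via golden-section search over integers with memoized full passes.
   Predictions at new locations refit the local regression centred there
   and back-transform through the Box-Cox inverse.
5. **Projection.** Climate scenarios replace only the temperature and
   precipitation layers, decade by decade; every other layer — and the
   fitted local coefficient field itself — is held fixed. This is pure
   space-for-time substitution: the spatial predictor-response gradient
   stands in for temporal change. Difference maps, per-ecoregion
   means/totals (Mg/ha, Tg, Pg) and decadal min/max/mean/total series
   summarize the result, and a block-mean comparison against a coarser
   external SOC raster is supported.
6. **Diagnostics.** Test-set R^2 is computed on the back-transformed
   Mg/ha scale (`1 - RSS/TSS`); regional bias is the signed mean residual
   and its magnitude as a percentage of the regional mean observed stock
   (the only definition consistent with published residual tables, where
   e.g. a region with mean stock 776.6 Mg/ha and mean residual
   -643.2 Mg/ha reports 82.8 %). A PCA of the correlation matrix of
   region-averaged local coefficients relates predictors to ecoregions.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| IQR fence multiplier `k` | 1.5 | — | the conventional Tukey fence |
| correlation threshold | 0.70 | `|r|` | strict inequality; pairs above it are collinear enough to destabilize coefficients |
| significance level `alpha` | 0.05 | — | applied to the overall F-test and each partial t-test |
| train fraction | 0.75 | — | 75/25 split (floor arithmetic: 4559 rows split 3419/1140) |
| kernel | bisquare | — | compact support pairs naturally with adaptive bandwidths; gaussian retained for the wide-bandwidth OLS limit |
| `k_range` | `[max(p+3, 10), n]` | neighbours | lower bound keeps local systems overdetermined |
| ridge jitter | 1e-8 | transformed scale | stabilizes locally singular systems (e.g. an indicator constant within a window) instead of dropping points, keeping the coefficient field complete |
| bandwidth floor | `1e-9 x` domain diagonal | m | coincident points can never produce a zero bandwidth |

Distances are planar Euclidean; lon/lat input switches to haversine
great-circle distances (`gwr_config(lonlat = TRUE)`), since synthetic
work is planar by default and the projection used for real pedon
coordinates is an open question for the user to settle upstream.

## What the synthetic landscape emulates

`generate_landscape()` partitions a regular grid (the 800 m analogue)
into contiguous Voronoi "ecoregions". Continuous predictors are white
noise convolved with a Gaussian kernel (the correlation length is the
kernel standard deviation in cells) and standardized exactly to mean 0,
variance 1; categorical layers are quantile-thresholded smooth fields
emitted as one-hot indicators with the reference class dropped, avoiding
the dummy-variable trap. The ground truth is a spatially varying
coefficient surface per predictor plus intercept; observations are drawn
at distinct cells, given Gaussian noise on the transformed scale, and
reported as stocks through the inverse Box-Cox transform (noise is
redrawn up to 100 times when a draw lands outside the inverse's domain
`lambda z + 1 > 0`, then the generator fails loudly). Profiles are then
synthesized backwards: layer boundaries tile 0--100 cm, concentrations
and densities are drawn positive and rescaled so the stock formula
reproduces the observation exactly.

The default study conditions use `lambda = 0.1`, intercept surface
`7 +/- 0.8`, and mean effects of -0.5 (temperature), +0.4
(precipitation) and +0.3 (NDVI) on the transformed scale, which yields
strongly right-skewed stocks centred near 230 Mg/ha — the shape and
magnitude of real continental pedon collections. What the generator does
*not* emulate: real marginal distributions of climate rasters,
cross-correlated predictor fields, anisotropy, measurement error in
depth or bulk density, and preferential (non-uniform) pedon siting.
Passing tests therefore demonstrate the estimator's correctness under
the assumed data-generating process, not performance on any real survey.

Two experiment-design choices deserve emphasis:

* **Predictor roughness vs coefficient smoothness.** The
  coefficient-recovery experiment uses rough predictor fields
  (correlation length 2 cells) under smooth coefficient surfaces
  (15 cells). This is not incidental: a predictor that is smooth at the
  scale of the kernel window is locally indistinguishable from the
  intercept, and its local coefficient is unidentifiable no matter how
  much data there is. Recovery claims are conditional on within-window
  predictor variation.
* **Transform scale in recovery experiments.** Coefficient recovery is
  measured with the response transformed at the generator's true
  exponent, isolating the spatial estimator from marginal lambda
  estimation, which is validated separately (the profile-likelihood
  search recovers exponents 0 and 0.5 to within 0.1 at n = 2000). In the
  end-to-end pipeline the exponent is estimated from the training
  stocks, as it would be in practice; the marginal estimate can differ
  noticeably from the generating exponent because the marginal stock
  distribution mixes the transform with spatial structure, and the
  pipeline is internally consistent either way.

## Numerical choices and degenerate inputs

* Quartiles use linear interpolation between order statistics (type 7),
  the common default.
* Bandwidth search is golden-section over integers with memoized AICc
  evaluations; ties resolve to the smaller k. Candidates whose hat-trace
  violates `n - 2 - tr S > 0` are treated as infinitely bad; if all do,
  the search errors rather than guessing.
* Exact ties in adjusted R^2 during subset selection resolve to the
  smaller subset, then lexicographic predictor order, making selection
  deterministic.
* The Box-Cox back-transform is the naive inverse; no smearing
  correction is applied, so back-transformed predictions are biased low
  for the conditional mean — consistent with the systematic
  underestimation that residual tables from this kind of analysis show
  in high-stock regions. Undefined inverses become missing cells with a
  logged count; they are never clamped.
* The scenario generator's zero floor on precipitation only binds for
  baselines that are already non-negative (physical rasters); for
  standardized anomaly fields it is a no-op, so the prescribed
  multiplicative drift is never clipped.
* Rasters are serialized as ESRI ASCII grids with a YAML manifest per
  stack: a plain-text, GIS-readable format with cell-centre
  registration; values round-trip at full double precision.

## Known limitations

* Selection honours its stated alpha semantics, with the corollary that
  with m pure-noise candidates the probability of recovering the exact
  support is about `(1 - alpha)^m` (~77 % for five decoys at 0.05):
  spurious but individually significant predictors are admitted by
  design, as they would be by any unadjusted F-test protocol.
* No mixed (partially global) GWR, no per-predictor multiscale
  bandwidths, no spatial autocorrelation tests on residuals, and no
  kriging of residuals.
* The coarse-grid comparison uses simple block means of fine cell
  centres, not area-weighted reprojection — adequate on the synthetic
  planar grids it serves.
* Equal-area planar cells are assumed when converting Mg/ha to Tg/Pg
  totals.

## Problem sizes

The shipped tests and the acceptance script run the recovery experiment
on a 60 x 60 cell landscape with 800 observations (600 train / 200
test), the selection study at n = 500 with 100 replicates, and the
end-to-end pipeline on a 30 x 30 landscape with 300 observations —
sizes at which every stage's behaviour is already asymptotic enough to
check the claims above while keeping a full run interactive.
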