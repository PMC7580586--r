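---
title: "Trace-element basemaps and likelihood-of-origin assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace-element basemaps and likelihood-of-origin assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Migratory bats killed at wind-energy facilities can in principle be traced
back to their summer molting grounds through the chemistry of their fur: the
concentrations of trace elements a bat incorporates while growing new fur
reflect, through the food web, the element composition of the local soil,
which varies over continental scales. `elementscape` implements the full
assignment pipeline for this idea: summarize a 14-element fur concentration
panel (Al, Ni, Cu, Rb, Y, Mo, Sn, Ba, Cs, Ce, Hg, Mg, Mn, Fe, all in ppb)
into a spatially weighted principal component; interpolate a continuous
"elementscape" basemap of predicted component values over a species range;
convert an individual's component score into a per-cell likelihood-of-origin
surface; and evaluate how accurately and precisely such surfaces recover
known origins.

Because individual elements couple only weakly to soil (per-element
fur-soil R² below ~0.16 in the reference data bundled with the package), no
single element can source an individual; the pipeline's premise is that a
multivariate summary can.

## Pipeline and model

### Synthetic landscape

Real continental soil-geochemistry surveys and museum fur collections are
not shippable, so the package generates landscapes with the statistical
structure the analysis assumes. Each element's soil surface is

    soil_e(x, y) = baseline_e + gradient_e . (x - x0, y - y0)
                   + sum_k A_ek exp(-d_k(x,y)^2 / (2 L_e^2)),

truncated at zero: a baseline plus a linear trend plus Gaussian bumps with
uniform-random centres, giving tunable spatial autocorrelation with a
closed-form ground truth. Fur is a weak linear transfer of soil at the true
origin plus noise, truncated at zero:

    fur_e = a_e + b_e * soil_e(origin) + N(0, noise_e).

The `"default"` preset is the study-like condition: per-element transfer
R² mostly below 0.16 and fur SD above half the mean (high inter-individual
dispersion). Concentration scales come from the bundled published fur means
so magnitudes are realistic. The `"strong"` preset (low noise, strong
fields) and the `"none"` preset (essentially flat soil, zero transfer slope,
fur pure noise) bracket the default for power analyses; `"none"` keeps a
vanishingly small soil gradient (1e-6 of baseline per degree) so the
transfer regressions stay well-posed while carrying no usable signal.

Truncation at zero, rather than log-normal sampling, keeps the generator
simple; heavy right tails (the reference Fe SD exceeds its mean) can be
emulated by raising bump amplitudes. The default extent mimics the aspect of
eastern North America (24 x 16 degrees) but is abstract — no coastline, no
real geochemistry, and a rectangular default range. What passing tests on
this generator show is that the *machinery* recovers known structure under
the stated statistical conditions; they cannot show that real fur chemistry
carries that structure.

The generator is deterministic from `seed`: soil fields, origins and noise
use separate derived streams (`seed`, `seed + 1`, `seed + 2`), and all
generator calls restore the caller's RNG state.

### Grid conventions

All rasters are regular lon/lat grids (WGS84 decimal degrees), default cell
0.16 degrees (~315 km² at mid latitudes), stored north-west origin with cell
centres at `origin + (index + 0.5) * cell_size`. Degrees are the grid unit
because the cells are specified in degrees; every physical distance
(bandwidths, IDW weights, buffers) is a haversine great-circle distance in
km. Raster IO uses the plain-text ESRI ASCII grid format; range polygons are
GeoJSON, rasterized by a centre-in-polygon test (even-odd rule, so holes are
respected).

### Outlier screening

Profiles are screened by squared robust Mahalanobis distance under a
minimum-covariance-determinant location/scatter estimate, flagging samples
beyond the chi-square quantile with one df per element. The cutoff quantile
defaults to 0.975 — a conventional choice, made explicit and configurable
because the screening rule in the original workflow involved visual
inspection that an automated pipeline cannot reproduce. Flagging never drops
samples implicitly; `drop_outliers()` is a separate, deliberate step. The
MCD subset search is randomized in general; the implementation canonicalizes
row order and fixes the search's RNG state internally so flags are
deterministic and order-invariant, without touching the caller's seed.

### Geographically weighted PCA

At each sample location `i`, the element panel (standardized per element to
zero mean and unit SD — correlation scale) is decomposed by an
eigenanalysis of the kernel-weighted covariance, with bisquare weights
`w_j = (1 - (d_ij/b_i)^2)^2` for `d_ij < b_i`. The bandwidth is adaptive by
default: `b_i` is the distance to the `k`-th nearest sample, with `k`
chosen by leave-one-out cross-validation (reconstruction error after
projecting each held-out standardized profile onto the leading local
component fitted without it), over candidates spanning 10-100% of the
sample size. The weighted covariance uses the unbiased correction
`1/(1 - sum w²)`, so the uniform-kernel, global-bandwidth limit reproduces
global PCA (n-1 denominator) exactly — a property the tests assert to 1e-8.

Design choices that were genuinely open:

* **Correlation-scale fit.** The reference loading table spreads PC1 across
  elements whose raw variances differ by four orders of magnitude (Fe SD
  ~80 ppb with loading −0.02); under a raw-covariance PCA the
  high-variance elements would absorb the leading component entirely, so
  the local covariance is computed on standardized data.
* **Raw-concentration scoring.** An individual's score is the dot product
  of its *raw* ppb concentrations with the summary loading vector. The
  reference per-individual PC values are all positive (15.29–97.99) and the
  sum of the published PC1 weights (loading × mean concentration) is 15.30,
  matching the printed minimum — centred or standardized scores would
  straddle zero. Standardized scoring is implemented behind
  `mode = "standardized"`.
* **Loading summary.** How location-varying local loadings collapse to one
  loading set per component is not specified anywhere; the package aligns
  each location's vector to the first location's (sign flip on negative dot
  product), takes the element-wise mean (median available), renormalizes to
  unit norm, and fixes the sign so the largest-magnitude entry is positive.
  The same largest-entry-positive convention is applied to every local
  eigenvector, making results reproducible across LAPACK backends.
* **Retention.** Components are retained by the Kaiser rule (mean local
  eigenvalue > 1 on the correlation scale); downstream stages use PC1.
* **Permutation test.** The spatial-structure test statistic is Moran's I
  of the PC1 scores with inverse-distance weights (the simplest spatial
  statistic; computed with `ape`), with scores permuted over locations and
  `p = (1 + #{perm >= obs}) / (n_perm + 1)`. Constant scores return p = 1
  with a warning.

### Basemap

The **direct portion** interpolates the training samples' PC1 scores by
inverse distance weighting — `w_j = d_j^(-power)` on haversine distances,
power 2 (the conventional GIS default), global neighbourhood — and extends
only to the convex hull of the sampling locations (configurable buffer,
default 0). A cell containing samples takes their mean exactly. The
**indirect portion** covers the rest of the range: each cell's soil vector
is pushed through the per-element transfer regressions (OLS of fur on soil)
to a hypothetical fur profile, truncated at zero, and scored with the same
summary loadings. The portions are merged with *no* blending or seam
smoothing — any misalignment is kept so the more accurate direct portion
stays exact — and out-of-range cells are no-data.

The assignment dispersion sigma is the residual SD (n−2 denominator) of the
OLS of actual on predicted scores. Because IDW honours its nodes, in-sample
predictions at training cells are degenerate (residuals ~0); the default
calibration therefore predicts each training sample by leave-one-out IDW
from the others. The published calibration value 9.696 is available via
`reference_sigma()`; the printed statement is internally ambiguous about
whether it is a variance or an SD, and the package reads it as a variance
(sigma = sqrt(9.696) ≈ 3.114) because the symbol attached to it is squared,
with `mode = "sd"` to flip the interpretation.

### Assignment

The likelihood that an individual with score `y*` originated in cell `i`
with predicted value `mu_i` is the normal density

    f(y* | mu_i, sigma) = (1 / (sigma sqrt(2 pi))) exp(-(y* - mu_i)^2 / (2 sigma^2)).

The raw density cannot exceed `1/(sigma sqrt(2 pi))` (≈ 0.128 at
sigma ≈ 3.11), yet assignment probabilities are conventionally read on a
0–1 scale; the package therefore normalizes by that maximum, giving
`f_i = exp(-(y* - mu_i)^2 / (2 sigma^2))`, which is 1 exactly where
`mu_i = y*`. The raw density is available with `normalize = FALSE`.

Classification: an individual is correct when the surface value at the cell
containing its true location reaches the threshold (default 0.5, compared
with `>=`, so exact ties count), and otherwise is rescued when any cell
whose *centre* lies within 10 km (a nightly foraging flight) reaches the
threshold — the centre rule, rather than cell-polygon overlap, keeps the
buffer test deterministic. Precision is the range fraction: the area share
of in-range cells at or above the threshold, with cos(latitude)-corrected
cell areas so degree cells count correctly at high latitude. Smaller range
fractions are better (more informative surfaces).

### Evaluation

`leave_k_out_cv()` repeats, 100 times by default: hold out k = 3
individuals (drawn independently per replicate — the original description
does not constrain overlap across replicates); refit the summary loadings,
transfer regressions, basemap and sigma from the n−3 training samples
(re-estimating sigma inside the replicate avoids leakage; a fixed sigma
mirroring the published single global value is supported); assign each
held-out individual; classify at 0.5/0.66/0.75 with the 10-km rescue.
Accuracy pools all held-out assignments; precision averages range fractions
over **correct individuals only** — an incorrect assignment's surface says
nothing about how tightly a correct one constrains the origin. (The
published mean precision of 47% is inconsistent with the mean of the
printed correct-only column, ~54%; the package computes the documented
formula and does not chase the printed summary.) The bandwidth is selected
once on the full design and held fixed across replicates; re-selection per
replicate is possible but would mostly add noise at these sample sizes.

## Worked example

```r
library(elementscape)

cfg <- landscape_config(seed = 1)        # 0.16-deg cells, 126 individuals
sim <- simulate_landscape(cfg)

screen   <- flag_outliers(sim$profiles)
profiles <- drop_outliers(sim$profiles, screen)

bw    <- select_bandwidth(profiles)
model <- fit_gwpca(profiles, as.numeric(bw))
variance_table(model)

reg <- fit_element_regressions(profiles, soil_at_locations(sim$soil, profiles))
bm  <- build_basemap(profiles, model, sim$soil, reg)

y1   <- score_samples(model, profiles)$PC1[1]
surf <- likelihood_surface(y1, bm)
probability_at(surf, profiles$lon[1], profiles$lat[1])
range_fraction(surf, full_range_mask(sim$soil$template))

report <- leave_k_out_cv(profiles, sim$soil, k = 3, reps = 100,
                         bandwidth = as.numeric(bw), seed = 2)
report
```

The numbered drivers under `analysis/` run exactly this sequence stage by
stage and leave their tables under `results/`.

## Numerical choices and degenerate inputs

* Eigenvector signs: largest-magnitude entry positive, everywhere.
* Weighted covariance uses the `1/(1 - sum w²)` unbiased correction.
* IDW distances are floored at 1 m (1e-9 km^-tolerance) before powering;
  cells containing samples bypass the weighting entirely.
* Concentrations are truncated at zero at generation and after the
  hypothetical-fur transform; ingest rejects negative or missing values
  outright.
* Degenerate inputs error loudly rather than degrade: collinear sample
  hulls, zero-variance soil predictors, constant standardized elements,
  singular MCD scatters, perfect sigma calibrations (residuals all zero),
  out-of-extent lookups, k >= n cross-validation.
* Points on the extreme north/east grid edges are clamped into the adjacent
  cell so the closed extent maps cleanly.

## Problem sizes

The test-suite fixtures use 12–500 individuals on coarse grids (0.4–1
degree cells) so the whole suite runs in well under a minute; the
signal-versus-noise comparison uses n = 60 with 30 replicates of
leave-three-out on a 0.8-degree grid. The acceptance script runs the full
default conditions — 126 individuals, 0.16-degree cells (100 x 150 grid),
100 leave-three-out replicates — in a few minutes. These sizes are the
package's choices for a desk-scale, fully reproducible analysis.

## Limitations

* The synthetic landscape has Gaussian-bump soil fields and raw-linear
  soil-to-fur transfer; real geochemistry has sharper lithological
  boundaries, anisotropy and skewed concentration distributions, and the
  transfer through a food web need not be linear (a log-scale transfer is a
  plausible alternative the generator does not default to, matching the
  linear-model usage it emulates).
* Assignment uses a single global sigma; spatially varying calibration
  error is not modelled (a per-region sigma hook exists but is off by
  default).
* No kriging or geostatistical interpolators; IDW only.
* No multi-marker fusion (isotopes, genetics) and no occupancy priors —
  surfaces are chemistry-only likelihoods.
* Range fractions depend on the range mask supplied; with the default
  full-grid mask they are upper bounds on what a real, smaller range would
  give.
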