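# elementscape

Geographic assignment of migratory wildlife from trace-element tissue
chemistry.

Bats killed at wind-energy facilities are mostly migrants, and mitigating
the impact requires knowing where they came from. Fur grown at the summer
molting site records the trace-element signature of the local environment:
element concentrations travel from soil through the food web into keratin,
and they vary over continental scales. `elementscape` turns that idea into a
working pipeline for researchers in movement ecology and wildlife forensics:
it summarizes multi-element fur concentration panels of known-origin
individuals, builds a continuous spatial basemap ("elementscape") of
predicted chemistry over a species range, converts an unknown individual's
chemistry into a likelihood-of-origin surface, and quantifies how accurate
and precise such assignments are.

## The method

For a panel of 14 elements (Al, Ni, Cu, Rb, Y, Mo, Sn, Ba, Cs, Ce, Hg, Mg,
Mn, Fe; ppb), one row per individual with its sampling coordinates:

1. **Screening.** Outlying profiles are flagged by squared robust
   Mahalanobis distance (MCD estimator, chi-square cutoff).
2. **Geographically weighted PCA.** At each sample location the
   correlation-scale element panel is decomposed under a bisquare kernel
   whose adaptive bandwidth is chosen by leave-one-out reconstruction
   error. Local loadings are summarized to one loading set per component;
   components with mean eigenvalue > 1 are retained (Kaiser rule);
   individuals are scored on PC1 as `y* = concentrations . loadings`.
3. **Basemap.** Inside the convex hull of the samples, PC1 scores are
   interpolated by inverse distance weighting (`w = d^-2`, haversine km);
   beyond it, soil element grids are pushed through per-element fur~soil
   transfer regressions to "hypothetical fur" and scored with the same
   loadings. The two portions are merged without seam smoothing.
4. **Assignment.** For an individual with score `y*` and a cell with
   predicted value `mu_i`, the likelihood of origin is the normal density

   `f(y* | mu_i, sigma) = (1 / (sigma sqrt(2 pi))) exp(-(y* - mu_i)^2 / (2 sigma^2))`

   normalized by its maximum to a 0-1 scale. An individual is assigned
   correctly when the value at its true cell reaches 0.5, or when any cell
   centre within 10 km (a nightly foraging flight) does; precision is the
   latitude-corrected share of the range at or above the threshold.
5. **Evaluation.** Leave-three-out cross-validation, 100 replicates:
   loadings, regressions, basemap and sigma are rebuilt from each training
   set, the held-out individuals assigned back, and accuracy/precision
   pooled, with a 0.5 / 0.66 / 0.75 threshold sweep.

A synthetic-landscape module generates soil grids (baseline + gradient +
Gaussian bumps) and known-origin individuals with the statistical structure
the analysis assumes — weak per-element fur-soil coupling (R² < 0.16), high
inter-individual dispersion (SD ≥ half the mean) — so the whole pipeline is
reproducible at desk scale without external databases. Small published
reference tables for eastern red bat (*Lasiurus borealis*) fur are bundled
for worked examples.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
landscape (126 individuals, 0.16-degree cells):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen_and_link.R
Rscript analysis/03_gwpca.R
Rscript analysis/04_basemap.R
Rscript analysis/05_assign_evaluate.R
```

which prints, stage by stage:

```
simulated 126 individuals over a 100 x 150 grid (0.16 deg cells)
fur dispersion (SD/mean) ranges 0.55-0.76 across elements
outlier screen: 26 of 126 flagged (cutoff chi2 = 26.1), 100 retained
fur-soil coupling: R-squared 0.003-0.264, 8 element(s) with p < 0.05
bandwidth selected by LOO CV: 70 neighbours (candidates 10, 25, 40, 55, 70, 85, 100)
PC1 explains 16% of variance; Kaiser rule retains 6 component(s)
Moran's I of PC1 scores: 0.094 (permutation p = 0.005, 199 perms)
basemap: 13730 direct cells, 1270 indirect cells; sigma = 15.053 (sigma^2 = 226.590)
direct vs indirect surface correlation at 150 random cells: 0.68
evaluation_report: 100 reps x 3 held out (n = 100, seed 1)
  pooled accuracy 0.743, mean probability 0.721
  range fraction over correct: mean 0.758 (min 0.028, max 0.980)
threshold sweep:
 threshold  accuracy mean_range_fraction
      0.50 0.7433333           0.7579085
      0.66 0.6233333           0.6506428
      0.75 0.5600000           0.5873210
```

Reading this: on a deliberately weak-signal landscape the individual
elements barely track soil (max R² 0.26), yet the spatially weighted PC1 is
significantly spatially structured (Moran's I permutation p = 0.005) and
74% of held-out individuals are assigned back to their origin at the 0.5
threshold — but with poor precision (76% of the range remains plausible on
average), the expected accuracy-over-precision trade-off at this signal
level. Raising the threshold trades accuracy for precision. Tables and
rasters land under `results/` (CSV, ASCII grid, JSON).

The same steps are available as ordinary functions (`simulate_landscape()`,
`flag_outliers()`, `select_bandwidth()`, `fit_gwpca()`, `build_basemap()`,
`likelihood_surface()`, `leave_k_out_cv()`, ...); see the vignette in
`vignettes/trace-element-assignment.Rmd` for the model, the open design
choices and their rationale, and known limitations.

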