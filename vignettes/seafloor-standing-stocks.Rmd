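---
title: "Modelling global seafloor standing stocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global seafloor standing stocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthicstocks)
```

## The problem

Benthic standing stocks — the biomass (mg C m^-2^) and abundance
(individuals or cells m^-2^) of bacteria, meiofauna, macrofauna, and
megafauna living on the sea floor — are controlled largely by the rain of
particulate organic carbon (POC) sinking out of the surface ocean. Stocks
decline roughly log-linearly with water depth, but the decline interacts
with surface productivity, water-column export, and bottom-water
conditions, so simple depth regressions fall apart in global predictive
mapping. `benthicstocks` implements the full inference chain used for this
kind of global synthesis:

1. **standardization** of heterogeneous stock records to a carbon currency,
   including adjustment of depth-integrated bacterial stocks to a common
   sediment penetration depth;
2. **partial-regression depth trends** per size class (latitude and
   longitude held constant);
3. a **regression random forest** — bootstrap-resampled, un-pruned binary
   trees with random predictor subsetting — with out-of-bag (OOB) error and
   accuracy-based permutation importance, written in this package (tree
   growth in compiled code) rather than delegated to an external library;
4. a **four-scenario ensemble** that refits the forest under increasingly
   strict satellite-coverage data selection to measure model stability;
5. **global prediction** on a 1° grid with per-cell mean and coefficient of
   variation, inverse-distance-weighted (IDW) smoothing, Jenks
   natural-breaks classification, and area-weighted global and zonal
   integrals of biomass, down to the residence time of seafloor living
   carbon.

Because the observational database and the real predictor stacks are not
redistributable, the package ships a first-class synthetic generator
(`gen_bathymetry()`, `gen_predictor_grids()`, `gen_stock_records()`) whose
defaults encode the study conditions, so every stage is testable end to end
against a known generative truth.

## Standardization

Biomass reported as wet or dry weight is converted to mg C m^-2^ with a
per-(class, unit) factor table (`default_conversion_table()`; organic
carbon as ~4.3% of wet and ~40% of dry weight). The defaults are
literature-style placeholders: real analyses should supply study-specific
factors (`standardize_units(strict = TRUE)` refuses the defaults).

Depth-integrated bacterial stocks depend on how deep the sediment was
cored (0.5–29.5 cm in typical databases, most between 5 and 15 cm).
`standardize_penetration()` regresses log10 stock on penetration depth —
jointly with latitude and longitude by default, since sampling depth
covaries with region — and replaces each value by
`residual + fitted(reference)`. The reference defaults to 10 cm, the
center of the 5–15 cm band. If every record shares one penetration depth
there is nothing to standardize and the operation is the identity.

Average body size is biomass/abundance, reported in µg C individual^-1^;
individuals above 10 mg C (10^4^ µg) are flagged as extremely large
because such outliers (high-latitude shelf fauna) can tilt size–depth
regressions.

## Partial regression

`partial_regression(y, lat, lon, depth)` fits stage 1, OLS of the log10
stock on latitude and longitude, adds the stage-1 intercept back to the
residuals (so the adjusted response keeps its scale), then fits stage 2,
OLS of the adjusted response on depth, reporting the slope, F statistic,
and a significance flag at P < 0.001. Longitude is used in raw degrees —
the dateline discontinuity is accepted rather than hidden — and a constant
covariate is dropped so degenerate designs collapse gracefully.

One property matters for interpreting recovery experiments: on a fixed
sample the two-stage slope equals `b (1 - R²_d)` where `R²_d` is the R² of
depth on (lat, lon) in that sample. Our synthetic worlds have
`R²_d ≈ 0.002–0.05` depending on continental geometry, so the estimator is
attenuated by up to a few percent relative to the generative slope. The
test suite therefore checks (i) exact agreement with the closed-form
two-stage value and (ii) recovery of the generative slope after undoing the
design attenuation, which is computable from the design alone.

```{r partial-example}
bathy <- gen_bathymetry(1, n_lat = 36, n_lon = 72)
world <- gen_predictor_grids(2, bathy)
world <- gen_stock_records(default_truth(), world, 300, seed = 3)
rec <- subset(world$records, size_class == "macrofauna")
partial_regression(log10(rec$biomass_mgC_m2), rec$latitude,
                   rec$longitude, rec$depth_m)
```

## The regression random forest

`fit_forest()` grows `n_trees` (default 1000) un-pruned regression trees.
Design choices, all of which the oracle tests pin down:

* **Resampling.** "Two thirds in-bag" is read as the standard bootstrap
  (n draws with replacement; expected unique fraction ≈ 63.2%), matching
  the classic forest algorithm; an exact-2/3 subsample mode
  (`sampling = "subsample"`) is available for sensitivity.
* **Split search.** At each node a fresh random subset of
  `mtry = ceiling(p/3)` predictors (13 of the 39) is scanned exhaustively;
  candidate thresholds are midpoints between consecutive distinct values;
  the split maximizing the reduction in sum of squared error wins. Ties are
  broken toward the lowest predictor index, then the lowest threshold, so a
  fit is a pure function of (data, hyperparameters, seed).
* **Stopping.** Nodes are split while both children can hold at least
  `min_leaf` samples (default 5, the customary regression-forest terminal
  size); a node with zero response variance becomes a leaf.
* **OOB error.** The OOB prediction for sample *i* averages only trees
  where *i* was never drawn. Performance is percent variance explained,
  `R² = 1 - MSE_OOB / var(y)` with the population variance of the observed
  response; it can be negative.
* **Importance.** For each tree and predictor, the tree's OOB MSE is
  recomputed after permuting that predictor among the tree's own OOB
  samples; the increase, averaged over the forest, is the accuracy
  importance. A single permutation per (tree, predictor) is used, with
  `n_rep` available for averaging. A constant predictor has importance
  exactly zero. Conditional permutation schemes for correlated predictors
  are out of scope; with 39 mutually correlated predictors, importance is
  read as "contribution to prediction accuracy", not causal attribution.

A single full-bag tree with `mtry = p` reproduces an independently written
exhaustive-search CART oracle exactly, and the OOB R² agrees with the
`randomForest` package on shared data — those are tests, not dependencies.

## Scenarios and importance combination

Productivity predictors derived from ocean-color satellites lose temporal
coverage toward the poles (winter darkness, cloud). `run_simulations()`
refits the forest under four data selections — all records, then records
whose cell had more than 30, 60, and 90 months of coverage — and reports
mean ± SD of R² and importance across the four runs. By default the four
scenario forests share one derived RNG stream, so scenarios holding
identical data yield bitwise-identical forests and the SD isolates the
effect of the data selection; `reseed_scenarios = TRUE` gives each run its
own stream instead. Importance SD is taken across the four simulations
(not across trees). `combine_importance()` pools per-scenario importance
across the four major classes for biomass only — the one response with a
common currency — and refuses abundance ensembles.

## Mapping and integrals

`grid_predict()` predicts every ocean cell with a complete 39-predictor
vector, per scenario, in log10 space; the cell mean, SD, and CV
(SD/mean x 100%) are computed on the log10 predictions (a linear-space
alternative is available via `cv_space`). Back-transformation is the naive
`10^x` — no lognormal correction is applied by default because the
published workflow used none; `combine_classes(bias_correction = TRUE)`
applies `10^(m + ln(10)/2 * s²)` using the cross-scenario SD for users who
want it. Class totals are summed in linear mg C m^-2^; a cell missing any
class is NA under the default strict policy.

IDW refinement to 0.1° uses power 2 and 12 neighbors (standard GIS
defaults; the source workflow does not state its values), planar degree
distances with longitude wrapped at the dateline, exact-hit reproduction at
coincident centers, and the coarse land mask preserved. Jenks breaks are
the exact Fisher dynamic program, deterministic, and match a brute-force
partition oracle for small n.

The global integral follows the equidistant-cylindrical prescription:

> integral = Σ cell value (mg C m^-2^) × A₀ × cos(latitude),

with A₀ = 12343 km², the printed equatorial 1° cell area. On an R = 6371 km
sphere the exact 1° cell area is ≈ 12364 km², an ≈ 0.2% discrepancy that we
document (and bound in tests against a closed-form spherical oracle) rather
than silently correct. Unit bookkeeping: 1 Mt C = 10^15^ mg. Zonal
integrals use half-open lower-inclusive 100-m depth bins or 2° latitude
bins with the same weighting, so bin masses sum to the global integral to
floating-point accuracy. Residence time is standing mass divided by net
throughput, `mass / (POC flux - burial)`, in days when the inputs are
Mt C and Mt C day^-1^.

## The synthetic world

The generator emulates the statistical structure the analysis assumes — no
ocean physics:

* **Bathymetry.** Continents come from a smoothed Gaussian random field;
  ocean depth increases with distance from land, with band boundaries
  placed on area-weighted quantiles so 6% of ocean area is shelf (< 200 m)
  and 75% abyssal (> 3000 m), mirroring real hypsography.
* **Predictors.** The 39 grids share a latitudinal forcing and a common
  spatially correlated anomaly (weight 0.8), plus short-range (≈ 3°)
  Gaussian-field noise per variable, giving productivity pairwise
  correlations ≥ 0.5 by construction — the real predictor stack is highly
  collinear, and tests must face that. Water-column stocks and fluxes decay
  with depth; bottom-water properties are smooth functions of depth and
  latitude. Coverage months are 120 equatorward of 50° and decline
  linearly to the poles.
* **Records.** `log10 stock = a + b·depth + c_lat·lat + c_lat2·lat² +
  c_lon·lon + f(predictors) + ε`. The default intercepts and depth slopes
  are the canonical global depth-decline coefficients for the four major
  classes (bacterial stocks essentially depth-independent, metazoans
  declining); `c_lat2` defaults to 0 and exists for polar-enhancement
  experiments. Sampling is biased toward shelves and the northern
  hemisphere as real databases are (`location_bias = FALSE` gives a clean
  uniform design for recovery tests). Bacterial records carry a
  penetration depth: 90% uniform on 5–15 cm, 10% spread over the rest of
  0.5–29.5 cm.
* **Noise calibration.** Published syntheses of this kind do not state
  their residual noise, so the defaults were fixed once: σ = 0.35 log10
  units everywhere except macrofauna biomass (0.5 — the largest and most
  heterogeneous dataset), with predictor-effect weights of a few tenths on
  surface-productivity variables. Under these defaults the four-scenario
  mean OOB R² of each class falls in the 63–88% band reported for real
  data (≈ 0.79/0.78/0.81/0.74–0.79 depending on seed), and scenario SDs
  stay below 3%.

What the generator does **not** emulate: mesoscale structure, seasonal
cycles, seep/vent/canyon anomalies, foraminifera, or realistic covariance
between depth and productivity beyond their shared latitude structure.
Passing tests therefore demonstrate that the machinery is correct and
well-calibrated on data with the assumed structure — not that the method's
field-data conclusions are reproduced here.

One consequence worth stating plainly: with the canonical Table-style
coefficients, the bacterial *abundance* depth slope (−3.58×10^-5^ per m) is
small but nonzero, and at n ≈ 515 a regression has nontrivial power to
detect it. The published analogue was reported as non-significant; in our
replicate experiments we therefore assert the *contrast* (bacterial F an
order of magnitude below the weakest metazoan F, bacterial biomass
non-significant in every replicate) rather than forcing per-replicate
non-significance of a truly-nonzero slope.

## Problem sizes

The test suite exercises most operations on a 36 × 72 (5°) world with a few
hundred records, and the acceptance-level checks on the full 180 × 360 (1°)
lattice with 600 records per class and 200-tree forests — sizes chosen so
the whole suite completes in a few minutes while the 1° runs still cover
every code path at production resolution. `scripts/acceptance.R` runs the
same 1° pipeline (200 trees by default; `--n_trees 1000` reproduces the
canonical forest size at ~5× the cost) and writes its headline quantities
as JSON.

## Known limitations

* Importance values of correlated predictors are diluted and partially
  interchangeable; rankings are stable, attributions are not.
* IDW and the cell-area formula work in planar lat/lon degrees; there is no
  map projection machinery, and polar cells are strongly anisotropic.
* The back-transform of mean log10 predictions estimates a median-like
  quantity; global integrals built from it are conservative relative to a
  lognormal mean (the optional bias correction addresses this).
* `read_records()` validates ranges and invariants but does not attempt
  taxonomic or gear-level harmonization; sieve-size effects are treated as
  negligible relative to depth, as is customary at global scale.
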