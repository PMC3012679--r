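# benthicstocks

Modelling and mapping global seafloor standing stocks — the biomass
(mg C m⁻²) and abundance (individuals m⁻²) of benthic size classes
(bacteria, meiofauna, macrofauna, megafauna) — from gridded environmental
predictors. The package is aimed at benthic ecologists and carbon-cycle
modellers who need a tested, reproducible version of the standard global
synthesis workflow, plus a synthetic-data generator that makes every stage
verifiable against a known truth.

## What it implements

* **Record standardization** — unit conversion to a carbon currency,
  adjustment of depth-integrated bacterial stocks to a common sediment
  penetration depth (partial regression on penetration, latitude,
  longitude), body size as biomass/abundance, CSV and KML I/O with
  row-level validation.
* **Partial-regression depth trends** — stage 1 removes latitude and
  longitude by OLS (intercept added back to the residuals), stage 2
  regresses the adjusted log10 stock on depth:
  `Y = a + bX`, with F test and significance at P < 0.001; also the
  latitude-parabola variant (depth and longitude removed, quadratic
  latitude fit).
* **A regression random forest**, authored here with compiled tree growth:
  bootstrap resampling, un-pruned binary trees, best split over a random
  `mtry = ⌈p/3⌉` predictor subset by SSE reduction, out-of-bag prediction,
  `R² = 1 − MSE_OOB / var(y)`, and permutation importance (increase of a
  tree's OOB MSE after permuting one predictor among its OOB samples,
  averaged over the forest).
* **Coverage scenarios** — four refits per dataset keeping records with
  >0 / >30 / >60 / >90 months of satellite coverage; mean ± SD of R² and
  importance measure stability; cross-class importance combination for
  biomass.
* **Global mapping and integrals** — per-cell scenario mean and CV on a 1°
  grid, IDW refinement to 0.1°, exact Fisher–Jenks class breaks, and
  area-weighted integrals
  `Σ value · A₀ · cos(lat)` (A₀ = 12343 km²) giving megatons of carbon
  globally, per 100-m depth bin, and per 2° latitude bin, down to the
  residence time of seafloor living carbon, `mass / (POC flux − burial)`.
* **A synthetic world** — bathymetry with shelf/slope/abyss structure (75%
  abyssal area), 39 mutually correlated predictor grids, poleward-declining
  coverage months, and stock records drawn from known log-linear truths —
  the test bed for everything above.

## A worked example

```r
library(benthicstocks)

bathy <- gen_bathymetry(1, n_lat = 36, n_lon = 72)   # 5-degree demo world
world <- gen_predictor_grids(2, bathy)
world <- gen_stock_records(default_truth(), world, 300, seed = 3)

rec <- subset(world$records, size_class == "macrofauna")
partial_regression(log10(rec$biomass_mgC_m2), rec$latitude,
                   rec$longitude, rec$depth_m)
#> log10 stock (n = 300): Y = 3.37-(0.000503) X;  F = 456.8, P < 0.001

ens <- run_simulations(world$records, world, "biomass", "macrofauna",
                       n_trees = 200, seed = 5)
ens
#> scenario_ensemble: macrofauna biomass, 4 scenario(s)
#>   n = 300/296/285/261; R^2 = 0.818/0.819/0.807/0.805 (mean 0.812, SD 0.0071)
#>   top predictors: depth, si.mean, det.c, phos.mean, temp.mean

pg  <- grid_predict(ens, world)
lin <- combine_classes(list(pg))          # back-transform to mg C m-2
global_integral(lin)
#> [1] 6.9579       # megatons of macrofaunal carbon on this demo world
```

The depth slope recovered by the partial regression (−5.03 × 10⁻⁴ per m)
sits next to the generative truth (−5.15 × 10⁻⁴, attenuated by the small
sample correlation between depth and latitude); the forest explains ~81%
of log10 biomass variance, stable within ~1% across the four coverage
scenarios; and `depth` tops the importance ranking, as it should for a
stock generated with a strong depth decline.

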