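# insulametrics

Modelling the drivers of vascular-plant richness and narrow endemism on
Mediterranean islands and archipelagos.

Island floras broadly obey the species–area power law *S = cA^z*, but the
*proportion* of narrow endemics — taxa confined to a single island or
archipelago — does not. Endemism tracks whatever interrupts gene flow:
rugged internal terrain and isolation from neighbouring landmasses. This
package implements that analysis end to end for an eight-island sample
(Corsica, Crete, Sardinia, Sicily, Cyprus, and the Maltese, Balearic and
Tuscan archipelagos):

* **Geospatial metrics** — `roughness_index()`: mean absolute elevation
  difference between each grid point and its immediate neighbours (queen or
  rook), from ESRI ASCII or plain-matrix elevation grids;
  `isolation_index()`: the fraction of a fixed-radius survey disc (default
  300 km) not occupied by neighbouring land, from binary land/sea rasters,
  with `choose_radius()` implementing the incremental radius-selection
  rule.
* **Data** — `load_island_fixture()`: the packaged eight-island table
  (topography, isolation, area, population density, taxon and endemic
  counts), plus validated CSV I/O.
* **Models** — `fit_negative_binomial()`: NB2 log-link count regression
  with ML dispersion; `fit_beta_regression()`: logit-link beta regression
  with constant precision (ML, in-package); `best_subsets()`: AICc-ranked
  model selection over predictor subsets; `model_report()` and
  `predict_surface()` for table- and surface-style outputs.
* **Synthetic data** — seeded generators for terrain
  (`generate_dem()`), coastlines (`generate_land_sea()`) and island tables
  drawn from the models' own generative forms
  (`generate_island_table()`), so every stage is testable offline.

## Worked example

```r
library(insulametrics)

tab <- load_island_fixture()
pearson_r(tab$Spp, tab$Area)
#> [1] 0.8342285

fit_species_area_power_law(tab)
#> Species-area power law: S = 425.3 * A^0.1787 (log-log r = 0.850)

nb <- best_subsets(tab, "count", specs = count_model_specs())
nb$summary[1, c("label", "predictors", "aic", "aicc")]
#>   label      predictors      aic     aicc
#> 1    C1 Area+Topography 108.1955 121.5289

nb$fits[["C1"]]
#> Negative binomial (NB2, log link) fit of Spp on {Area, Topography}
#>   theta = 265.05 (ML), logLik = -50.098, AIC = 108.20, AICc = 121.53
#>   deviance: null 216.07, residual 8.07 (96.3% explained)

fit_beta_regression(tab, "Topography")
#> Beta regression (logit link) fit of Prop on {Topography}
#>   phi = 43.02, logLik = 15.245, AIC = -24.49, AICc = -18.49
#>   pseudo-R2 = 0.407
```

Reading: taxon counts rise with area (r = 0.834; 0.850 after log-log
transform). Among the five standard count models, the two-predictor
area + topography model ranks first, explaining 96.3% of the null deviance
with both predictors significant — topography matters for richness, not
just area. For the endemic *proportion*, topography is the one predictor
that stays significant in every model (Wald p = 0.015 in the
single-predictor fit), with isolation joining it in the richer models.

`reproduce_tables("results/reproduction")` runs the whole fixture analysis
(correlations, count suite A1–E1, proportion suite A2–D2, prediction
surface) and writes report CSVs plus a run manifest; reruns are
byte-identical. The numbered scripts under `analysis/` are narrative
drivers: `01` the published-data analysis, `02` the geospatial metrics on
synthetic terrain and coastlines, `03` a parameter-recovery and
subset-selection simulation study.

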