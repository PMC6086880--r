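# borealgrowth

Climate sensitivity of boreal tree growth from tree-ring basal area
increments, with scenario projection of stand growth under warming and
precipitation change.

## The problem

Boreal forests in Eastern North America grow under strong temperature
limitation in the north and increasing water limitation in the south.
Whether moderate warming helps or hurts a given species depends on where a
site sits along these gradients, and on local conditions: soil, competition,
stand age, snowfall. `borealgrowth` implements a complete
space-for-time analysis pipeline for this question, aimed at quantitative
forest ecologists and dendroclimatologists working with forest-inventory
tree-ring collections:

1. **Tree-ring preparation** — dated ring widths are converted to annual
   basal area increments (BAI, cm² yr⁻¹) from the bark inward using the
   measured DBH as the outer value; Tukey's rule (k = 3) screens outlier
   rings; growth is averaged over each tree's 10–15 most recent years
   within a fixed study period.
2. **Climate** — monthly FAO-56 Penman–Monteith potential
   evapotranspiration (PET) and the climate moisture index
   CMI = Prec − PET, summarised as growing-season (May–September) and
   summer (June–August) totals, plus mean annual daily maximum temperature
   (T_MAX) and January–March snowfall.
3. **Stand structure** — symmetric competition BA (total basal area per
   hectare, nested-plot expansion factors 25/250/16) and asymmetric
   competition BAL (basal area of strictly larger trees).
4. **Growth model** — per species, a penalized additive model

   ```
   log(BAI + 1) = β + log(Size) + Size + f(Age) + f(BAL) + f(BA)
                + f(T_MAX) + f(CMI) + f(T_MAX, CMI) + f(Slope)
                + ε_soil + ε_snow + ε_stage + ε
   ```

   with cubic regression splines bounded to basis dimension 4, a
   scale-invariant tensor-product interaction bounded to 3 per margin,
   factor-modified smooths for soil/snow/stage, REML smoothness selection
   (mgcv), and Duan's smearing retransformation
   `BAI = exp(η) · S − 1`, `S = mean(exp(residuals))`, to remove the
   log-transform back-bias. AIC selects among T_MAX/T_MEAN ×
   CMI_GS/CMI_SUMMER; an 80/20 split reports test-set RMSE.
5. **Projection** — fitted models are applied to a 2-cm DBH-class stem
   inventory under scenarios of +1…+4 °C warming (coupled to a PET
   increase of 43.25 mm °C⁻¹, i.e. 43–173 mm) and −5…+15 % growing-season
   precipitation change, with locally varying patterns; plot growth per
   hectare is averaged over 15-km polygons and summarised as zone mean
   change ± SE and the fraction of polygons declining, with a
   climate-space guard that reports the fraction of stems projected within
   the observed temperature range.

Because real inventory tree-ring data of this kind are licensed, the
package ships a first-class **synthetic-data generator**: a planar
landscape with a latitudinal temperature gradient and a longitudinal
moisture gradient, circular sample plots with nested stem tables, and
cored trees whose ring widths are back-computed from a known growth
response surface (`ground_truth()`). Every stage of the pipeline is
validated by parameter recovery against that surface.

## Worked example

```r
library(borealgrowth)

# simulate a landscape, plots, cored trees and a stem inventory from a
# known truth with an 8 degC thermal optimum
sim <- simulate_dataset(seed = 42, n_cells_x = 14, n_cells_y = 14,
                        n_plots = 1250, trees_per_plot = 4,
                        truth = ground_truth(t_opt = 8, sigma_log = 0.3),
                        species_probs = c(black_spruce = 1))

# rings -> BAI -> screened, windowed tree observations with covariates
prep <- prepare_tree_observations(sim$series, sim$plot_covariates, sim$stems)

# fit the additive growth model
m <- fit_growth_model(prep$observations, model_spec())
print(m)
#> Additive growth model on log(BAI + 1)
#>   n = 5000, deviance explained = 97.6%, RMSE = 3.4%, AIC = -9062.9
#>   smearing factor: 1.0047

fitted_t_opt(m)
#> [1] 7.899305
```

The fitted temperature partial effect peaks at 7.90 °C against a
generating optimum of 8.0 °C — the pipeline recovers the thermal threshold
to within 0.1 °C at this sample size. Projecting a stem inventory under
the scenario grid (`project_growth_change()`) then yields zone-mean growth
changes that rise for +1 to +2 °C of warming and shrink or reverse at
+4 °C — the transitory-benefit pattern — together with the fraction of
15-km polygons declining and the climate-space guard fraction.

A staged, config-driven version of the same chain (CSV/JSON artifacts, run
manifest) is available as `run_pipeline("all", config)` or from the shell
via `inst/scripts/run_pipeline.R`.

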