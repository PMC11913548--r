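# gilashift

Dispersal-constrained habitat forecasting for the Gila monster
(*Heloderma suspectum*) in the Mojave Desert — and, more generally, a
tested pipeline for any analysis that chains presence-only ensemble
habitat modeling, telemetry-based movement modeling, decadal climate
projection with a reachability-limited occupancy update, and
protected-area gap tabulation.

A species can only occupy newly suitable habitat it can reach. For a
philopatric, slow-moving lizard, a warming scenario that shifts suitable
habitat upslope may strand it: habitat appears, but beyond dispersal
range. gilashift makes that constraint explicit. The pipeline is aimed at
spatial ecologists and conservation planners who want range-shift
forecasts that respect movement biology, and it is fully exercisable on
synthetic landscapes with a known truth — the study species' real
localities are withheld because of poaching risk.

## The models

**Habitat.** An ensemble of four presence-background learners — random
forest (regression mode), gradient-boosted trees, a binomial GAM, and an
L1-regularized logistic MaxEnt-family model — fit to spatially thinned
presences (one per 250 m cell, ≤ 4 per 1000 m cell) against
pseudo-absences drawn where a Bioclim climate envelope scores below 0.05,
weighted by a kernel-density sampling-effort surface. Twenty
cross-validation iterations withhold 20% of presences; per algorithm,
models above the median held-out AUC are averaged with TSS weights
`w_i = TSS_i / ΣTSS`, the algorithm ensembles combine by mean TSS, the
standard error is `sd(p_i)/√k`, and the binary map thresholds at the
maximum of sensitivity + specificity. Evaluation: AUC, TSS, the
continuous Boyce index (Spearman correlation of P/E ratios over 101
sliding windows), and Sørensen similarity `2TP/(2TP+FN+FP)`.

**Movement.** Telemetry filtered to actual movements (> 40 fixes, > 1
year, steps ≥ 50 m, no bridge over gaps > 36 h) feeds per-animal Brownian
bridge movement models: position at time fraction α between fixes is
Normal about the connecting line with variance
`Tα(1−α)σ²m + (1−α)²δ² + α²δ²`, with σ²m estimated by leave-one-out
likelihood. One hundred points sampled uniformly over each surface (above
a 1e-8 cutoff) feed a mixed-effects regression of log occurrence
probability on terrain, shrub cover, habitat suitability and log
road/path distances with a per-animal random intercept.

**Projection.** Decadal climate covariates (November–March precipitation
totals, March–May temperature means), delta-downscaled and
cubic-spline-resampled to the modeling grid, drive per-decade suitability
with the fitting-period threshold. Occupiable habitat updates as
`O_d = (O_{d−1} ∩ S_d) ∪ R_d`, where reachable cells `R_d` are newly
suitable cells within 3 km of prior occupiable habitat, above the 1st
percentile of movement predictions at the model's localities, and under
20% impervious surface. The headline number per scenario is final over
initial occupiable area.

**Gap analysis.** Habitat overlaid on protection categories with
precedence bookkeeping (nested Designated counts as Proclamation;
tribal/defense lands removed; state/NGO Fee parcels merged into
Proclamation; solar zones tabulated as an overlay).

## A worked example

```r
library(gilashift)

grid  <- raster_grid(0, 15000, 250, 60, 60)      # 60 x 60 cells @ 250 m
stack <- make_landscape(grid, seed = 101)         # synthetic covariates
truth <- truth_params()
suit  <- true_suitability(stack, truth)           # known truth in [0, 1]

occ <- sample_occurrences(suit, stack[["effort"]], 600, seed = 11)
eff <- sample_occurrences(suit, stack[["effort"]], 300, seed = 12)
cfg <- pipeline_config(cv_iterations = 5, random_seed = 13)

prep <- prep_occurrences(occ, eff, grid, cfg)
prep$thinning
#> <gs_thinning> 444 -> 311 points (max 4 per 1000 m cell, seed 13)

ens <- fit_ensemble_sdm(prep$presences, stack, prep$bias, cfg)
glance(ens)
#> # A tibble: 1 x 6
#>   n_candidates n_algorithms threshold mean_auc mean_tss mean_boyce
#>          <int>        <int>     <dbl>    <dbl>    <dbl>      <dbl>
#> 1            8            4     0.446    0.986    0.905      0.517

cv_metric_report(ens$cv)
#> # A tibble: 4 x 4
#>   algorithm   auc  boyce   tss
#>   <chr>     <dbl>  <dbl> <dbl>
#> 1 gam       0.986 0.472  0.890
#> 2 gbm       0.977 0.704  0.871
#> 3 maxent    0.969 0.0307 0.852
#> 4 rf        0.980 0.544  0.897

pred <- ensemble_predict(ens, stack)
cor(as.vector(pred$mean$values), as.vector(suit$values),
    method = "spearman")
#> [1] 0.838
```

The 600 raw records collapse to 444 after one-per-cell deduplication and
311 after coarse-grid thinning. Cross-validated AUC near 0.99 and a rank
correlation of 0.84 between the ensemble mean and the generating truth
say the model recovers the suitability surface it was shown, despite the
detection-biased sampling. `autoplot(pred$mean)` maps the prediction;
`tidy(ens)` lists the candidate models and weights.

From there, `simulate_telemetry()` + `filter_telemetry()` +
`bbmm_surface()` + `fit_movement_model()` + `predict_movement()` build
the movement surface, `make_future_climate()` +
`run_decadal_projection()` produce the per-decade occupiable series
(`autoplot()` draws the occupiable / newly-suitable / reachable lines),
and `resolve_precedence()` + `tabulate_gap()` give the protection table.

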