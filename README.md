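# ensdm

Ensemble species distribution modelling with TSS-weighted ensembles,
cutoff-anchored habitat classification, and centroid-shift analysis — as
a tested, reproducible R pipeline.

`ensdm` is aimed at spatial ecologists who run BIOMOD2-style climate
impact assessments: presence records and a stack of bioclimatic/terrain
rasters go in; out come a 0–1000 habitat-suitability surface from a
performance-gated weighted ensemble, a four-class habitat map, equal-area
class statistics and change rates across climate scenarios, and
area-weighted centroid shifts with geodesic distances and compass
sectors.  Every stage is exercised against a synthetic world with known
ground truth, so the machinery is testable without downloading occurrence
archives or climate layers.

## The model in brief

* Records are cleaned by fixed-order rules (coordinates, 0.01° precision,
  provenance flags, degenerate coordinates, domain, 200–2200 m elevation,
  year ≥ 1970) and thinned to one record per grid cell.
* Predictors are screened by pairwise correlation (remove the
  lower-priority member of any pair with |r| ≥ 0.80) followed by stepwise
  elimination of variance inflation factors > 10.
* Pseudo-absences are sampled outside a 5-km buffer around presences;
  equal-prevalence weighting gives each presence weight 1 and each
  pseudo-absence weight n_presence / n_pa, so class weight sums match
  (187 presences vs 10,000 pseudo-absences ⇒ 0.0187 each).
* Pluggable probabilistic learners are fitted over 3 pseudo-absence sets
  × 5 stratified 75/25 splits; replicates with held-out
  TSS = sensitivity + specificity − 1 ≥ 0.70 form a weighted-mean
  ensemble with weights ∝ TSS, scaled to 0–1000.
* The ensemble's TSS-maximizing integer cutoff separates suitable from
  unsuitable habitat; Jenks natural breaks on the baseline suitable cells
  (anchored so the unsuitable class ends at the cutoff) define
  low/moderate/high classes frozen across all scenarios.
* Class areas use the exact spherical band formula (authalic radius
  6371.0072 km); centroids are area-weighted means in an Albers
  equal-area conic projection; shifts are Vincenty geodesics on WGS84
  classified into eight compass sectors.

See `vignettes/ensdm-methods.Rmd` for assumptions, parameter defaults,
numerical choices, and what the synthetic world does and does not
emulate.

## Worked example

```r
library(ensdm)

spec  <- grid_spec(n_rows = 80, n_cols = 80, lon_min = 100, lat_max = 32,
                   cell_size = 0.1)
stack <- generate_stack(spec, n_layers = 6, corr_length = 8, seed = 1)
truth <- true_suitability(default_true_model(), stack)
occ   <- sample_occurrences(truth, n = 150, seed = 2,
                            contamination = contamination_spec())

occ <- clean_records(occ, cleaning_rules(domain = c(100, 108, 24, 32)))
occ <- validate_on_stack(thin_records(occ, spec), stack)

sam <- build_screening_sample(stack, occ, n_background = 2000, seed = 3)
scr <- screen_predictors(sam)
pa  <- draw_pseudo_absences(stack, occ, n_per_set = 2000, n_sets = 2,
                            buffer_km = 5, seed = 4)
models <- fit_replicates(list(learner_glm_quad(), learner_ridge(),
                              learner_sre()),
                         stack, occ, pa, layers = scr$retained,
                         n_repeats = 3, seed = 5)
evals <- evaluate_replicates(models)
summarize_performance(evals)
#>    learner n roc_mean roc_sd tss_mean tss_sd
#> 1 glm_quad 6    0.955 0.0152    0.857 0.0394
#> 2    ridge 6    0.952 0.0162    0.843 0.0400
#> 3      sre 6    0.775 0.0572    0.551 0.1143
```

The GLM and ridge replicates discriminate well (mean TSS ≈ 0.85); the
range envelope is weak, as expected.  Build the gated ensemble and
project a warming scenario:

```r
ens <- calibrate_ensemble(build_ensemble(models, evals, gate = 0.70))
ens
#> <ensemble_model> 13 replicates (gate TSS >= 0.70), cutoff 407

current <- ensemble_predict(ens, stack)
warm    <- apply_scenario(stack, scenario_delta("SSP585-2090s",
             shift = c(bio7 = 1.6, bio18 = -0.8), scale = c(bio7 = 1.15)))
future  <- ensemble_predict(ens, warm)

breaks  <- anchored_classification(current, cutoff = ens$cutoff)
areas   <- cell_areas(spec)
tab_cur <- area_table(classify_map(current, breaks), areas)
tab_fut <- area_table(classify_map(future,  breaks), areas)
attr(tab_fut, "scenario_id") <- "SSP585-2090s"

cs <- change_stats(tab_cur, tab_fut)
#> total suitable: 10.67 -> 5.04 x10^4 km^2 (-52.77%); core rate: -50.76%
```

All 13 replicates clearing the TSS gate form the ensemble; the warming
scenario halves the total suitable area.  The 407/1000 cutoff is this
toy run's TSS-optimal threshold — real analyses will find their own.
Centroid shifts and variable importance:

```r
shift_table(list(current = classify_map(current, breaks),
                 "SSP585-2090s" = classify_map(future, breaks)), areas)
#>    scenario_id   scope distance_km   sector area_1e4km2 caveat
#> 1      current overall           0 Original       10.67  FALSE
#> 2 SSP585-2090s overall         208        E        5.04  FALSE
#> 3      current    core           0 Original        4.47   TRUE
#> 4 SSP585-2090s    core         233        E        2.20   TRUE

permutation_importance(ens, n_perm = 10, seed = 6)
#>   rank layer importance n_permutations
#> 1    1  bio7     0.5789             10
#> 2    2  elev     0.3952             10
#> 3    3 bio18     0.3599             10
#> 4    4 bio19     0.1778             10
#> 5    5 bio15     0.0059             10
#> 6    6  bio3     0.0046             10
```

Both habitat centroids move ~200 km east under this scenario (the core
rows carry a small-area caveat: their supporting area is below the
5 × 10⁴ km² floor).  Importance recovers the generative ordering — bio7
strongest, the two decoy layers (bio3, bio15) near zero.

The same analysis runs end-to-end from one configuration:

```r
run_pipeline(run_config(out_dir = "run1", seed = 123), "all")
# or: Rscript -e 'ensdm::ensdm_main()' all --out run1 --seed 123
```

writing rasters (ESRI ASCII grids), CSV tables (performance, areas,
change rates, shifts, importance), JSON manifests, and an audit of every
dropped occurrence record under `run1/`.

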