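# Shared fixtures, all built in code.

# a small grid over a SW-China-like window
small_spec <- function(n = 20, cell = 0.1)
  grid_spec(n, n, lon_min = 100, lat_max = 30, cell_size = cell)

random_layer <- function(spec, seed = 1, n_masked = 0, name = "layer") {
  set.seed(seed)
  v <- matrix(rnorm(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
  mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
  if (n_masked > 0) {
    idx <- sample(length(v), n_masked)
    mask[idx] <- TRUE
    v[idx] <- 0
  }
  raster_layer(spec, v, mask, name = name)
}

# a fast, fully deterministic small world for pipeline-level tests:
# 40x40 grid, 4 signal + 1 decoy layers, glm-only learner set
small_world <- function(seed = 123, n_grid = 40, n_occ = 60,
                        n_pa = 500, n_sets = 2, n_repeats = 2,
                        learners = list(learner_glm_quad())) {
  spec <- grid_spec(n_grid, n_grid, 100, 30, 0.1)
  stack <- generate_stack(spec, n_layers = 5, corr_length = 4,
                          seed = derive_seed(seed, "stack"))
  truth <- true_suitability(default_true_model(), stack)
  occ <- sample_occurrences(truth, n_occ, seed = derive_seed(seed, "occ"))
  occ$status <- "retained"
  occ <- thin_records(occ, spec)
  occ <- validate_on_stack(occ, stack)
  pa <- draw_pseudo_absences(stack, occ, n_per_set = n_pa, n_sets = n_sets,
                             buffer_km = 0, seed = seed)
  models <- fit_replicates(learners, stack, occ, pa,
                           layers = c("bio7", "elev", "bio18", "bio19"),
                           n_repeats = n_repeats, seed = seed)
  evals <- evaluate_replicates(models)
  ens <- calibrate_ensemble(build_ensemble(models, evals, gate = 0.5))
  list(spec = spec, stack = stack, truth = truth, occ = occ,
       pa = pa, models = models, evals = evals, ens = ens)
}

# memoised copy so several test files can share one fitted world
shared_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- small_world()
    w
  }
})
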