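test_that("prevalence weights equalize class weight sums", {
  expect_equal(prevalence_weights(187, 10000)$pa, 0.0187)
  expect_equal(prevalence_weights(187, 10000)$presence, 1)
  expect_equal(prevalence_weights(100, 100)$pa, 1)
  expect_equal(prevalence_weights(50, 10000)$pa, 0.005)
  expect_error(prevalence_weights(0, 10), ">= 1")
})

test_that("splits are stratified, sized and reproducible", {
  labels <- c(rep(1, 100), rep(0, 100))
  sp <- make_splits(labels, frac = 0.75, n_repeats = 5, seed = 7)
  expect_length(sp, 5)
  for (s in sp) {
    expect_equal(length(s$calibration), 150)
    expect_equal(sum(labels[s$calibration]), 75)     # 75 presences
    expect_equal(sort(c(s$calibration, s$evaluation)), 1:200)
    expect_length(intersect(s$calibration, s$evaluation), 0)
  }
  # 5 distinct partitions, reproducible
  keys <- sapply(sp, function(s) paste(s$calibration, collapse = ","))
  expect_equal(length(unique(keys)), 5)
  sp2 <- make_splits(labels, frac = 0.75, n_repeats = 5, seed = 7)
  expect_identical(sapply(sp2, function(s) s$calibration),
                   sapply(sp, function(s) s$calibration))
  expect_error(make_splits(labels, frac = 1.0), "frac")
  expect_error(make_splits(c(1, rep(0, 10)), 0.75), "stratum")
})

test_that("pseudo-absence buffer excludes exactly the hand-enumerated ring", {
  # 9x9 grid of 0.1-degree cells straddling the equator: every cell is
  # ~11.13 km tall and wide, diagonal neighbors ~15.74 km away
  spec <- grid_spec(9, 9, 0, 0.45, 0.1)
  stack <- predictor_stack(list(raster_layer(spec, matrix(1, 9, 9),
                                             name = "bio7")))
  occ <- occurrence_table("p", lon = cell_center_lon(spec, 5),
                          lat = cell_center_lat(spec, 5),
                          precision_deg = 0.001, year = 2000L,
                          elevation_m = 800)
  occ$status <- "retained"
  # buffer 16 km spans ~1.5 cells: the 8 ring neighbors are excluded,
  # two-cell neighbors (>= 22.2 km) are not
  pa <- draw_pseudo_absences(stack, occ, n_per_set = 72, n_sets = 1,
                             buffer_km = 16, seed = 1)
  expect_error(draw_pseudo_absences(stack, occ, n_per_set = 73, n_sets = 1,
                                    buffer_km = 16, seed = 1), "eligible")
  drawn <- pa[[1]]$cells
  ring <- expand.grid(row = 4:6, col = 4:6)
  for (i in seq_len(nrow(ring)))
    expect_false(any(drawn[, "row"] == ring$row[i] &
                     drawn[, "col"] == ring$col[i]))

  # buffer 0: every valid non-presence cell is eligible
  pa0 <- draw_pseudo_absences(stack, occ, n_per_set = 80, n_sets = 1,
                              buffer_km = 0, seed = 1)
  expect_equal(nrow(pa0[[1]]$cells), 80)

  # determinism
  pa_a <- draw_pseudo_absences(stack, occ, 20, 2, 16, seed = 5)
  pa_b <- draw_pseudo_absences(stack, occ, 20, 2, 16, seed = 5)
  expect_identical(pa_a, pa_b)
  expect_false(identical(pa_a[[1]]$cells, pa_a[[2]]$cells))
})

test_that("buffer exclusion matches a brute-force distance check", {
  set.seed(21)
  spec <- grid_spec(12, 12, 100, 31, 0.1)
  stack <- predictor_stack(list(raster_layer(spec, matrix(1, 12, 12),
                                             name = "bio7")))
  pres_rc <- cbind(row = sample(12, 3), col = sample(12, 3))
  occ <- occurrence_table(letters[1:3],
                          lon = cell_center_lon(spec, pres_rc[, "col"]),
                          lat = cell_center_lat(spec, pres_rc[, "row"]),
                          precision_deg = 0.001, year = 2000L, elevation_m = 800)
  occ$status <- "retained"
  buffer <- 12
  n_elig <- local({
    cnt <- 0
    for (r in 1:12) for (cc in 1:12) {
      if (any(pres_rc[, "row"] == r & pres_rc[, "col"] == cc)) next
      dmin <- min(ensdm:::haversine_km(cell_center_lon(spec, cc),
                                       cell_center_lat(spec, r),
                                       cell_center_lon(spec, pres_rc[, "col"]),
                                       cell_center_lat(spec, pres_rc[, "row"])))
      if (dmin >= buffer) cnt <- cnt + 1
    }
    cnt
  })
  pa <- draw_pseudo_absences(stack, occ, n_per_set = n_elig, n_sets = 1,
                             buffer_km = buffer, seed = 3)
  expect_equal(nrow(pa[[1]]$cells), n_elig)
  expect_error(draw_pseudo_absences(stack, occ, n_per_set = n_elig + 1,
                                    n_sets = 1, buffer_km = buffer, seed = 3))
})

test_that("assembled datasets satisfy the weight-balance invariant", {
  w <- shared_world()
  for (pa in w$pa) {
    ds <- assemble_dataset(w$stack, w$occ, pa,
                           layers = c("bio7", "elev", "bio18", "bio19"))
    expect_equal(sum(ds$w[ds$y == 1]), sum(ds$w[ds$y == 0]), tolerance = 1e-9)
    expect_true(all(ds$w[ds$y == 1] == 1))
  }
})

test_that("fit_replicates counts, flags failures, and is deterministic", {
  w <- shared_world()
  learners <- list(learner_constant(0.5), learner_sre())
  models <- fit_replicates(learners, w$stack, w$occ, w$pa,
                           layers = c("bio7", "elev"), n_repeats = 2,
                           seed = 99)
  expect_length(models$replicates, 2 * 2 * 2)  # learners x sets x repeats

  # the constant test double predicts 0.5 on every row
  const_rep <- models$replicates[[1]]
  expect_equal(const_rep$learner, "constant")
  ds <- models$datasets[[1]]
  expect_true(all(ensdm:::predict_replicate(const_rep, ds$X) == 0.5))

  # a learner that errors flags its replicate without aborting
  bad <- base_learner("bad", fit = function(X, y, w, seed) stop("boom"),
                      predict = function(state, X) rep(0.5, nrow(X)))
  models2 <- fit_replicates(list(bad, learner_constant(0.2)), w$stack, w$occ,
                            w$pa, layers = c("bio7", "elev"), n_repeats = 2,
                            seed = 1)
  flags <- sapply(models2$replicates, function(r) r$failed)
  expect_equal(sum(flags), 4)
  evals2 <- evaluate_replicates(models2)
  expect_false("bad" %in% evals2$learner)
  expect_equal(nrow(evals2), 4)

  # determinism of the full default-learner fit at small scale
  fit_once <- function() {
    m <- fit_replicates(list(learner_glm_quad(), learner_ridge(),
                             learner_fda()), w$stack, w$occ, w$pa,
                        layers = c("bio7", "elev", "bio18", "bio19"),
                        n_repeats = 2, seed = 123)
    sapply(m$replicates, function(r)
      sum(ensdm:::predict_replicate(r, m$datasets[[r$set_index]]$X[1:50, ])))
  }
  expect_identical(fit_once(), fit_once())
})

test_that("all default learners honor the probability contract", {
  set.seed(4)
  n <- 400
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] - X[, 2]^2))
  wts <- ifelse(y == 1, 1, 0.5)
  for (ln in default_learners()) {
    st1 <- ln$fit(X, y, wts, seed = 11)
    p1 <- ln$predict(st1, X)
    expect_true(all(is.finite(p1)), info = ln$name)
    expect_true(all(p1 >= 0 & p1 <= 1), info = ln$name)
    st2 <- ln$fit(X, y, wts, seed = 11)
    expect_equal(ln$predict(st2, X), p1, tolerance = 1e-12, info = ln$name)
    # every learner beats chance in-sample on this separable problem
    expect_gt(roc_auc(p1, y), 0.5)
  }
})
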