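test_that("confusion_at_threshold counts by hand", {
  s <- c(900, 800, 700, 400, 300, 200)
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(confusion_at_threshold(s, y, 500),
               c(sensitivity = 1, specificity = 1))
  expect_equal(confusion_at_threshold(s, y, 750),
               c(sensitivity = 2 / 3, specificity = 1))
  # all scores 0 at t = 0: nothing predicted positive
  expect_equal(confusion_at_threshold(rep(0, 4), c(1, 1, 0, 0), 0),
               c(sensitivity = 0, specificity = 1))
  expect_error(confusion_at_threshold(1:3, c(1, 1, 1), 1))
})

test_that("roc_auc equals brute-force pair enumeration", {
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0)), 1)
  set.seed(31)
  for (trial in 1:100) {
    n <- 30
    s <- sample(0:1000, n, replace = TRUE)  # ties likely
    y <- rbinom(n, 1, 0.5)
    if (all(y == y[1])) y[1] <- 1 - y[1]
    expect_equal(roc_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("max_tss equals an independent exhaustive scan", {
  scan_tss <- function(s, y) {
    best <- list(tss = -Inf)
    for (t in 0:1000) {
      cs <- confusion_at_threshold(s, y, t)
      tss <- cs[[1]] + cs[[2]] - 1
      if (tss > best$tss + 1e-15) best <- list(threshold = t, tss = tss,
                                               sens = cs[[1]], spec = cs[[2]])
    }
    best
  }
  # spec'd hand example: smallest argmax
  mt <- max_tss(c(900, 800, 700, 400, 300, 200), c(1, 1, 1, 0, 0, 0))
  expect_equal(mt$threshold, 400)
  expect_equal(mt$tss, 1)
  # degenerate: constant scores
  mt0 <- max_tss(rep(500, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(mt0$tss, 0)
  set.seed(17)
  for (trial in 1:25) {
    n <- 40
    s <- sample(0:1000, n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (all(y == y[1])) y[1] <- 1 - y[1]
    got <- max_tss(s, y)
    want <- scan_tss(s, y)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$tss, want$tss, tolerance = 1e-12)
    # identity tss = sens + spec - 1 at the chosen threshold
    expect_equal(got$tss, got$sensitivity + got$specificity - 1,
                 tolerance = 1e-9)
  }
})

test_that("TSS from printed ensemble sensitivity/specificity is 0.914", {
  tss <- 0.97531 + 0.93900 - 1
  expect_equal(round(tss, 3), 0.914)
})

test_that("summarize_performance computes mean and sample SD", {
  ev <- data.frame(replicate_id = c("a:1", "a:2", "b:1"),
                   learner = c("a", "a", "b"),
                   auc = c(0.9, 0.9, 0.8), tss = c(0.8, 0.9, 0.7))
  out <- summarize_performance(ev)
  expect_equal(out$tss_mean[out$learner == "a"], 0.85)
  expect_equal(out$tss_sd[out$learner == "a"], sd(c(0.8, 0.9)))
  expect_equal(out$tss_sd[out$learner == "a"], 0.0707, tolerance = 1e-3)
  expect_equal(out$learner, c("a", "b"))  # sorted by mean TSS desc
  # identical replicates -> SD 0
  ev2 <- data.frame(replicate_id = c("c:1", "c:2"), learner = "c",
                    auc = 0.9, tss = 0.8)
  expect_equal(summarize_performance(ev2)$tss_sd, 0)
})

test_that("build_ensemble gates at TSS and normalizes proportional weights", {
  w <- shared_world()
  fake_evals <- function(tss) data.frame(
    replicate_id = w$evals$replicate_id[seq_along(tss)],
    learner = "x", auc = 0.9, tss = tss)
  e1 <- build_ensemble(w$models, fake_evals(c(0.8, 0.8)), gate = 0.7)
  expect_equal(e1$weights, c(0.5, 0.5))
  e2 <- build_ensemble(w$models, fake_evals(c(0.9, 0.6)), gate = 0.7)
  expect_equal(e2$weights, 1)
  expect_equal(length(e2$replicates), 1)
  e3 <- build_ensemble(w$models, fake_evals(c(0.9, 0.75, 0.72)), gate = 0.7)
  expect_equal(e3$weights, c(0.9, 0.75, 0.72) / 2.37, tolerance = 1e-12)
  expect_equal(e3$weights, c(0.3797, 0.3165, 0.3038), tolerance = 1e-4)
  expect_equal(sum(e3$weights), 1, tolerance = 1e-12)
  expect_error(build_ensemble(w$models, fake_evals(c(0.5, 0.4)), gate = 0.7),
               "no replicate")
})

test_that("ensemble_predict is the rounded weighted mean on the 0-1000 scale", {
  w <- shared_world()
  # constant test doubles with known weights
  mk_const <- function(p, id) {
    ln <- learner_constant(p)
    structure(list(learner = "constant", replicate_id = id, set_index = 1L,
                   split = w$models$replicates[[1]]$split,
                   center = w$models$replicates[[1]]$center,
                   scale = w$models$replicates[[1]]$scale,
                   state = list(p = p), predict = ln$predict, failed = FALSE),
              class = "replicate_model")
  }
  ens <- w$ens
  ens$replicates <- list(mk_const(0.2, "c1"), mk_const(0.6, "c2"))
  ens$weights <- c(0.5, 0.5)
  m <- ensemble_predict(ens, w$stack)
  expect_true(all(m$values[!m$nodata_mask] == 400))

  ens$replicates <- list(mk_const(1, "c1"), mk_const(1, "c2"))
  m2 <- ensemble_predict(ens, w$stack)
  expect_true(all(m2$values[!m2$nodata_mask] == 1000))

  ens$replicates <- list(mk_const(0.5, "c1"))
  ens$weights <- 1
  m3 <- ensemble_predict(ens, w$stack)
  expect_true(all(m3$values[!m3$nodata_mask] == 500))
})

test_that("ensemble map values stay inside the per-cell replicate envelope", {
  w <- shared_world()
  m <- ensemble_predict(w$ens, w$stack)
  valid <- which(!w$stack$nodata_mask)
  cells <- cbind(row = ((valid - 1) %% w$spec$n_rows) + 1,
                 col = ((valid - 1) %/% w$spec$n_rows) + 1)
  X <- ensdm:::design_at_cells(w$stack, cells, w$ens$layers)
  preds <- sapply(w$ens$replicates, function(r)
    ensdm:::predict_replicate(r, X))
  lo <- 1000 * apply(preds, 1, min); hi <- 1000 * apply(preds, 1, max)
  expect_true(all(m$values[valid] >= floor(lo) - 0.5))
  expect_true(all(m$values[valid] <= ceiling(hi) + 0.5))
})

test_that("gcm_mean averages cellwise and unions masks", {
  spec <- small_spec(6)
  mk <- function(vals, mask = NULL, elev = 5) predictor_stack(list(
    raster_layer(spec, matrix(vals, 6, 6), mask, "bio7"),
    raster_layer(spec, matrix(elev, 6, 6), mask, "elev")), "f")
  s1 <- mk(1); s3 <- mk(3)
  out <- gcm_mean(list(s1, s3))
  expect_true(all(out$layers$bio7$values == 2))
  expect_identical(gcm_mean(list(s1, s1))$layers$bio7$values,
                   s1$layers$bio7$values)
  # oracle: brute-force loop mean over three random stacks
  set.seed(5)
  vs <- replicate(3, matrix(rnorm(36), 6, 6), simplify = FALSE)
  stacks <- lapply(vs, function(v) predictor_stack(list(
    raster_layer(spec, v, NULL, "bio7"),
    raster_layer(spec, matrix(5, 6, 6), NULL, "elev")), "f"))
  got <- gcm_mean(stacks)$layers$bio7$values
  want <- matrix(0, 6, 6)
  for (r in 1:6) for (cc in 1:6)
    want[r, cc] <- mean(c(vs[[1]][r, cc], vs[[2]][r, cc], vs[[3]][r, cc]))
  expect_equal(got, want, tolerance = 1e-12)
  # differing elev is an error
  expect_error(gcm_mean(list(s1, mk(3, elev = 7))), "elev")
  # mask union
  mask <- matrix(FALSE, 6, 6); mask[1, 1] <- TRUE
  out2 <- gcm_mean(list(s1, mk(3, mask = mask)))
  expect_true(out2$nodata_mask[1, 1])
})

test_that("project_all reuses weights and cutoff across scenarios", {
  w <- shared_world()
  same <- w$stack
  shifted <- apply_scenario(w$stack, scenario_delta("warm", shift = c(bio7 = 1)))
  maps <- project_all(w$ens, list(same, shifted))
  expect_equal(length(maps), 2)
  base <- ensemble_predict(w$ens, w$stack)
  expect_identical(maps[[1]]$values, base$values)
  expect_equal(attr(maps[[2]], "cutoff"), w$ens$cutoff)
  expect_false(identical(maps[[1]]$values, maps[[2]]$values))
})
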