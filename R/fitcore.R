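#' Draw pseudo-absence sets outside a presence buffer
#'
#' Cells are sampled uniformly without replacement from valid cells whose
#' centers lie at least `buffer_km` (great-circle, authalic sphere) from
#' every presence cell center.  Each set gets its own deterministic
#' sub-seed, so sets are independent but reproducible.
#'
#' @param stack a [predictor_stack()].
#' @param presences an [occurrence_table()] validated on the stack.
#' @param n_per_set pseudo-absences per set (default 10000).
#' @param n_sets number of sets (default 3).
#' @param buffer_km exclusion radius around presence cells (default 5).
#' @param seed master seed.
#' @return list of `pseudo_absence_set` objects, each with `set_id`,
#'   `cells` (row/col matrix) and `seed`.
#' @export
draw_pseudo_absences <- function(stack, presences, n_per_set = 10000,
                                 n_sets = 3, buffer_km = 5, seed = 123) {
  spec <- stack$spec
  pc <- presence_cells(presences, spec)
  pres_idx <- (pc$col - 1L) * spec$n_rows + pc$row
  valid_idx <- setdiff(which(!stack$nodata_mask), pres_idx)
  row <- ((valid_idx - 1L) %% spec$n_rows) + 1L
  col <- ((valid_idx - 1L) %/% spec$n_rows) + 1L
  lon <- cell_center_lon(spec, col); lat <- cell_center_lat(spec, row)
  plon <- cell_center_lon(spec, pc$col); plat <- cell_center_lat(spec, pc$row)
  eligible <- rep(TRUE, length(valid_idx))
  if (buffer_km > 0) {
    ## only cells within a generous lat/lon window of some presence can
    ## possibly violate the buffer; check those with the haversine formula
    margin <- buffer_km / 110 + spec$cell_size
    near <- rep(FALSE, length(valid_idx))
    for (k in seq_along(plon))
      near <- near | (abs(lat - plat[k]) < margin &
                      abs(lon - plon[k]) < margin / max(cos(plat[k] * pi / 180), 0.05))
    if (any(near)) {
      dmin <- rep(Inf, sum(near))
      for (k in seq_along(plon)) {
        d <- haversine_km(lon[near], lat[near], plon[k], plat[k])
        dmin <- pmin(dmin, d)
      }
      eligible[near] <- dmin >= buffer_km
    }
  }
  pool <- valid_idx[eligible]
  if (length(pool) < n_per_set)
    stop("only ", length(pool), " eligible cells for ", n_per_set,
         " pseudo-absences")
  lapply(seq_len(n_sets), function(s) {
    sub_seed <- derive_seed(seed, "pseudo-absence", s)
    set.seed(sub_seed)
    pick <- sample(pool, n_per_set)
    structure(list(set_id = s,
                   cells = cbind(row = ((pick - 1L) %% spec$n_rows) + 1L,
                                 col = ((pick - 1L) %/% spec$n_rows) + 1L),
                   seed = sub_seed),
              class = "pseudo_absence_set")
  })
}

## great-circle distance on the authalic sphere, km
haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371.0072) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad; dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Equal-prevalence weights
#'
#' Presences get unit weight; each pseudo-absence gets
#' `n_presence / n_pa`, so the summed weights of the two classes are equal
#' and the effective prevalence is 0.5.
#'
#' @param n_presence,n_pa class sizes (>= 1).
#' @return list with `presence` and `pa` weights.
#' @export
prevalence_weights <- function(n_presence, n_pa) {
  if (n_presence < 1 || n_pa < 1) stop("both counts must be >= 1")
  list(presence = 1, pa = n_presence / n_pa)
}

#' Label-stratified calibration/evaluation splits
#'
#' Presence and pseudo-absence rows are partitioned separately at `frac`,
#' so both classes keep the intended calibration share even when heavily
#' imbalanced.  Each repeat draws from its own deterministic sub-seed.
#'
#' @param labels 0/1 label vector defining the strata.
#' @param frac calibration fraction (default 0.75; must be in (0, 1)).
#' @param n_repeats number of random repeats (default 5).
#' @param seed master seed.
#' @param set_id pseudo-absence set id recorded on the plans.
#' @return list of `split_plan` objects with `calibration` and
#'   `evaluation` row indices.
#' @export
make_splits <- function(labels, frac = 0.75, n_repeats = 5, seed = 123,
                        set_id = 1L) {
  n <- length(labels)
  if (n < 8) stop("need at least 8 rows")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  strata <- split(seq_len(n), labels)
  if (any(lengths(strata) < 2)) stop("every stratum needs at least 2 rows")
  lapply(seq_len(n_repeats), function(r) {
    sub_seed <- derive_seed(seed, "split", set_id, r)
    set.seed(sub_seed)
    cal <- sort(unlist(lapply(strata, function(idx)
      sample(idx, round(frac * length(idx)))), use.names = FALSE))
    structure(list(replicate_id = sprintf("set%d-rep%d", set_id, r),
                   set_id = set_id, repeat_index = r,
                   calibration = cal,
                   evaluation = setdiff(seq_len(n), cal),
                   seed = sub_seed),
              class = "split_plan")
  })
}

## design rows (matrix of layer values) at a set of cells
design_at_cells <- function(stack, cells, layers = names(stack$layers)) {
  idx <- (cells[, "col"] - 1L) * stack$spec$n_rows + cells[, "row"]
  mat <- vapply(stack$layers[layers], function(l) l$values[idx],
                numeric(length(idx)))
  matrix(mat, nrow = length(idx), dimnames = list(NULL, layers))
}

#' Assemble the weighted dataset for one pseudo-absence set
#'
#' @param stack screened [predictor_stack()].
#' @param presences validated [occurrence_table()].
#' @param pa_set one [draw_pseudo_absences()] element.
#' @param layers retained layer names (default: all stack layers).
#' @return list with `X` (design matrix), `y`, `w` and `cells`.
#' @export
assemble_dataset <- function(stack, presences, pa_set,
                             layers = names(stack$layers)) {
  pc <- as.matrix(presence_cells(presences, stack$spec))
  Xp <- design_at_cells(stack, pc, layers)
  Xa <- design_at_cells(stack, pa_set$cells, layers)
  wts <- prevalence_weights(nrow(Xp), nrow(Xa))
  list(X = rbind(Xp, Xa),
       y = c(rep(1L, nrow(Xp)), rep(0L, nrow(Xa))),
       w = c(rep(wts$presence, nrow(Xp)), rep(wts$pa, nrow(Xa))),
       cells = rbind(pc, pa_set$cells))
}

#' Fit all learner x pseudo-absence-set x repeat replicates
#'
#' For each replicate the design is standardized by the calibration rows'
#' mean/SD (stored with the model) and the learner is fitted on the
#' calibration rows with prevalence weights.  A learner failure flags
#' that replicate rather than aborting the run.
#'
#' @param learners list of [base_learner()] objects.
#' @param stack screened [predictor_stack()].
#' @param presences validated [occurrence_table()].
#' @param pa_sets list from [draw_pseudo_absences()].
#' @param layers retained layer names.
#' @param frac calibration fraction (default 0.75).
#' @param n_repeats repeats per set (default 5).
#' @param seed master seed.
#' @return object of class `replicate_models`: `replicates` (one entry per
#'   learner x set x repeat), `datasets` (one per set), `layers`.
#' @export
fit_replicates <- function(learners, stack, presences, pa_sets,
                           layers = names(stack$layers), frac = 0.75,
                           n_repeats = 5, seed = 123) {
  datasets <- lapply(pa_sets, function(s)
    assemble_dataset(stack, presences, s, layers))
  replicates <- list()
  for (ds_i in seq_along(datasets)) {
    ds <- datasets[[ds_i]]
    splits <- make_splits(ds$y, frac = frac, n_repeats = n_repeats,
                          seed = seed, set_id = pa_sets[[ds_i]]$set_id)
    for (sp in splits) {
      cal <- sp$calibration
      ctr <- colMeans(ds$X[cal, , drop = FALSE])
      scl <- apply(ds$X[cal, , drop = FALSE], 2, stats::sd)
      scl[scl == 0] <- 1
      Xc <- scale(ds$X[cal, , drop = FALSE], center = ctr, scale = scl)
      for (ln in learners) {
        fit_seed <- derive_seed(seed, "fit", ln$name, sp$replicate_id)
        set.seed(fit_seed)
        state <- tryCatch(ln$fit(Xc, ds$y[cal], ds$w[cal], fit_seed),
                          error = function(e) e)
        failed <- inherits(state, "error")
        replicates[[length(replicates) + 1L]] <- structure(
          list(learner = ln$name, replicate_id = paste0(ln$name, ":", sp$replicate_id),
               set_index = ds_i, split = sp, center = ctr, scale = scl,
               state = if (failed) NULL else state,
               predict = ln$predict, failed = failed,
               message = if (failed) conditionMessage(state) else NULL),
          class = "replicate_model")
      }
    }
  }
  structure(list(replicates = replicates, datasets = datasets,
                 layers = layers, seed = seed),
            class = "replicate_models")
}

## predict one replicate on raw (unstandardized) design rows
predict_replicate <- function(rep, X) {
  Xs <- scale(X[, names(rep$center), drop = FALSE],
              center = rep$center, scale = rep$scale)
  p <- rep$predict(rep$state, Xs)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("learner '", rep$learner, "' violated the probability contract")
  p
}
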