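#' Sensitivity and specificity at an integer threshold
#'
#' A record is predicted positive iff its score exceeds `t` (scores on the
#' 0-1000 suitability scale); counts are unweighted.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @param t threshold.
#' @return named vector `c(sensitivity, specificity)`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  stopifnot(any(labels == 1), any(labels == 0))
  pos <- scores > t
  c(sensitivity = sum(pos & labels == 1) / sum(labels == 1),
    specificity = sum(!pos & labels == 0) / sum(labels == 0))
}

#' Rank-statistic AUC
#'
#' Concordant-pair fraction with ties counted one half (the Mann-Whitney
#' U formulation of the area under the ROC curve).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(any(labels == 1), any(labels == 0))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' TSS-maximizing threshold by exhaustive integer scan
#'
#' Scans every threshold t in 0..1000 and returns the smallest t attaining
#' the maximum TSS = sensitivity + specificity - 1.
#'
#' @param scores scores on the 0-1000 scale.
#' @param labels 0/1 labels (both classes must be present).
#' @return list with `threshold`, `tss`, `sensitivity`, `specificity`.
#' @export
max_tss <- function(scores, labels) {
  stopifnot(any(labels == 1), any(labels == 0))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  t <- 0:1000
  ## cumulative counts of scores > t via tabulation on the integer scale
  s_clamp <- pmin(pmax(floor(scores), 0), 1000)
  pos_tab <- tabulate(s_clamp[labels == 1] + 1L, nbins = 1001L)
  neg_tab <- tabulate(s_clamp[labels == 0] + 1L, nbins = 1001L)
  ## TP(t) = number of positives with floor(score) > t  (scores integer)
  tp <- rev(cumsum(rev(pos_tab)))  # tp[i] = #pos with score >= i-1
  fp <- rev(cumsum(rev(neg_tab)))
  TP <- c(tp[-1], 0)               # score > t  <=>  score >= t+1
  FP <- c(fp[-1], 0)
  sens <- TP / n1
  spec <- (n0 - FP) / n0
  tss <- sens + spec - 1
  i <- which.max(tss)              # which.max returns the first maximum
  list(threshold = t[i], tss = tss[i],
       sensitivity = sens[i], specificity = spec[i])
}

#' Evaluate every replicate on its held-out rows
#'
#' Predictions are scaled to 0-1000 (round half away from zero) and
#' scored with [roc_auc()] and [max_tss()] on the evaluation partition.
#'
#' @param models a [fit_replicates()] result.
#' @return data.frame of evaluation records (one per non-failed
#'   replicate): `replicate_id`, `learner`, `auc`, `tss`,
#'   `best_threshold`, `sensitivity`, `specificity`.
#' @export
evaluate_replicates <- function(models) {
  recs <- lapply(models$replicates, function(rep) {
    if (rep$failed) return(NULL)
    ds <- models$datasets[[rep$set_index]]
    ev <- rep$split$evaluation
    p <- predict_replicate(rep, ds$X[ev, , drop = FALSE])
    s <- round_half_up(1000 * p)
    mt <- max_tss(s, ds$y[ev])
    data.frame(replicate_id = rep$replicate_id, learner = rep$learner,
               auc = roc_auc(s, ds$y[ev]), tss = mt$tss,
               best_threshold = mt$threshold,
               sensitivity = mt$sensitivity, specificity = mt$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Per-learner performance summary
#'
#' Mean and sample SD (n - 1) of AUC and TSS per learner, sorted by mean
#' TSS descending.
#'
#' @param evals an [evaluate_replicates()] data.frame.
#' @export
summarize_performance <- function(evals) {
  stopifnot(nrow(evals) >= 1)
  agg <- lapply(split(evals, evals$learner), function(d)
    data.frame(learner = d$learner[1], n = nrow(d),
               roc_mean = mean(d$auc), roc_sd = stats::sd(d$auc),
               tss_mean = mean(d$tss), tss_sd = stats::sd(d$tss),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(-out$tss_mean), ]
  rownames(out) <- NULL
  out
}

#' Build the TSS-gated proportional-weight ensemble
#'
#' Replicates with held-out TSS at or above the gate are retained and
#' weighted proportionally to their TSS (weights sum to 1).
#'
#' @param models a [fit_replicates()] result.
#' @param evals the matching [evaluate_replicates()] table.
#' @param gate minimum TSS for inclusion (default 0.70).
#' @return object of class `ensemble_model` holding the retained
#'   replicates, their weights, the gate, and (after
#'   [calibrate_ensemble()]) the TSS-maximizing cutoff.
#' @export
build_ensemble <- function(models, evals, gate = 0.70) {
  keep <- evals[evals$tss >= gate, , drop = FALSE]
  if (nrow(keep) == 0)
    stop("no replicate reached TSS >= ", gate,
         "; consider lowering the gate or inspecting the learners")
  w <- keep$tss / sum(keep$tss)
  ids <- vapply(models$replicates, function(r) r$replicate_id, character(1))
  retained <- models$replicates[match(keep$replicate_id, ids)]
  structure(list(replicates = retained,
                 replicate_ids = keep$replicate_id,
                 weights = w, tss = keep$tss, gate = gate,
                 cutoff = NA_integer_, evaluation = NULL,
                 datasets = models$datasets, layers = models$layers),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d replicates (gate TSS >= %.2f), cutoff %s\n",
              length(x$weights), x$gate,
              if (is.na(x$cutoff)) "unset" else x$cutoff))
  invisible(x)
}

## weighted-mean ensemble probability on raw design rows
predict_ensemble_rows <- function(ens, X) {
  p <- numeric(nrow(X))
  for (i in seq_along(ens$replicates))
    p <- p + ens$weights[i] * predict_replicate(ens$replicates[[i]], X)
  p
}

#' Evaluate the ensemble and fix its TSS-maximizing cutoff
#'
#' The ensemble is scored on the full presence + pooled pseudo-absence
#' dataset (presences once, all pseudo-absence rows) — apparent
#' evaluation, the construction closest to how ensemble-level scores and
#' the binarization cutoff are usually reported.  The resulting cutoff is
#' stored on the model and reused for every scenario.
#'
#' @param ens an [build_ensemble()] result.
#' @return the ensemble with `cutoff` set and an `evaluation` record
#'   (auc, tss, threshold, sensitivity, specificity).
#' @export
calibrate_ensemble <- function(ens) {
  pooled <- pooled_dataset(ens)
  p <- predict_ensemble_rows(ens, pooled$X)
  s <- round_half_up(1000 * p)
  mt <- max_tss(s, pooled$y)
  ens$cutoff <- as.integer(mt$threshold)
  ens$evaluation <- data.frame(auc = roc_auc(s, pooled$y), tss = mt$tss,
                               threshold = mt$threshold,
                               sensitivity = mt$sensitivity,
                               specificity = mt$specificity)
  ens
}

## presences once + every set's pseudo-absence rows
pooled_dataset <- function(ens) {
  ds1 <- ens$datasets[[1]]
  n_pres <- sum(ds1$y == 1)
  X <- ds1$X; y <- ds1$y; cells <- ds1$cells
  for (ds in ens$datasets[-1]) {
    pa <- ds$y == 0
    X <- rbind(X, ds$X[pa, , drop = FALSE])
    y <- c(y, ds$y[pa])
    cells <- rbind(cells, ds$cells[pa, , drop = FALSE])
  }
  list(X = X, y = y, cells = cells, n_presence = n_pres)
}

#' Project the ensemble onto a predictor stack
#'
#' Per valid cell, `S = round(1000 * sum(w_i p_i))` with rounding half
#' away from zero; masked cells stay nodata.
#'
#' @param ens a calibrated [ensemble_model].
#' @param stack a [predictor_stack()] carrying all model layers.
#' @return a `suitability_map`: an integer 0-1000 [raster_layer()] with
#'   `scenario_id` and the ensemble cutoff attached as attributes.
#' @export
ensemble_predict <- function(ens, stack) {
  missing <- setdiff(ens$layers, names(stack$layers))
  if (length(missing)) stop("stack lacks model layer(s): ",
                            paste(missing, collapse = ", "))
  valid <- which(!stack$nodata_mask)
  cells <- cbind(row = ((valid - 1L) %% stack$spec$n_rows) + 1L,
                 col = ((valid - 1L) %/% stack$spec$n_rows) + 1L)
  X <- design_at_cells(stack, cells, ens$layers)
  p <- predict_ensemble_rows(ens, X)
  m <- matrix(0, stack$spec$n_rows, stack$spec$n_cols)
  m[valid] <- round_half_up(1000 * p)
  out <- raster_layer(stack$spec, m, stack$nodata_mask,
                      name = paste0("suitability_", stack$scenario_id))
  attr(out, "scenario_id") <- stack$scenario_id
  attr(out, "cutoff") <- ens$cutoff
  class(out) <- c("suitability_map", class(out))
  out
}

#' Cellwise multi-model mean of predictor stacks
#'
#' Arithmetic mean per layer across stacks from different climate models;
#' masks are unioned.  The terrain layer `"elev"`, when present, must be
#' identical across inputs.
#'
#' @param stacks list of grid- and layer-compatible [predictor_stack()]s.
#' @param scenario_id label for the averaged stack (default: first input's).
#' @export
gcm_mean <- function(stacks, scenario_id = NULL) {
  stopifnot(length(stacks) >= 1)
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!same_grid(ref$spec, s$spec)) stop("grid mismatch between stacks")
    if (!identical(names(ref$layers), names(s$layers)))
      stop("layer sets differ between stacks")
    if ("elev" %in% names(s$layers) &&
        !isTRUE(all.equal(ref$layers$elev$values, s$layers$elev$values)))
      stop("'elev' must be identical across GCM stacks")
  }
  mask <- Reduce(`|`, lapply(stacks, function(s) s$nodata_mask))
  layers <- lapply(names(ref$layers), function(nm) {
    acc <- Reduce(`+`, lapply(stacks, function(s) s$layers[[nm]]$values))
    v <- acc / length(stacks)
    v[mask] <- 0
    raster_layer(ref$spec, v, mask, name = nm)
  })
  predictor_stack(layers, scenario_id = scenario_id %||% ref$scenario_id)
}

#' Project the ensemble onto every scenario stack
#'
#' The same weights and cutoff are applied to each scenario so
#' cross-scenario differences reflect only the climate inputs.
#'
#' @param ens a calibrated [ensemble_model].
#' @param stacks named or unnamed list of [predictor_stack()]s.
#' @return list of suitability maps, one per scenario.
#' @export
project_all <- function(ens, stacks) {
  maps <- lapply(stacks, function(s) ensemble_predict(ens, s))
  names(maps) <- vapply(stacks, function(s) s$scenario_id, character(1))
  maps
}
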