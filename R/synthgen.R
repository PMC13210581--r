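#' Generate a stack of smoothed, cross-correlated Gaussian random fields
#'
#' Each layer is white noise convolved with an isotropic Gaussian kernel
#' (SD `corr_length` cells, applied separably by row and column), then
#' standardized to mean 0 / SD 1 over valid cells.  Cross-layer correlation
#' is imposed by first whitening the smoothed fields (smooth fields have
#' few effective spatial degrees of freedom, so their sample correlations
#' stray far from zero) and then mixing with the Cholesky root of
#' `cross_corr`; realized correlations therefore match the target exactly.
#' Stands in for a bioclimate + terrain raster archive: the
#' layer named `"elev"` plays the role of the terrain layer that stays
#' constant across climate scenarios.
#'
#' @param spec a [grid_spec()].
#' @param n_layers number of layers.
#' @param corr_length spatial autocorrelation scale (kernel SD, in cells).
#' @param cross_corr target cross-layer correlation matrix (symmetric
#'   positive-definite, `n_layers x n_layers`); identity by default.
#' @param seed integer seed; output is fully deterministic given it.
#' @param layer_names layer names; default `bio...`-style names with the
#'   second layer called `"elev"`.
#' @param nodata_mask optional logical matrix of cells to mask.
#' @param scenario_id scenario label for the stack.
#' @return a [predictor_stack()] of standardized layers.
#' @export
generate_stack <- function(spec, n_layers = 6, corr_length = 8,
                           cross_corr = NULL, seed = 123,
                           layer_names = NULL, nodata_mask = NULL,
                           scenario_id = "current") {
  stopifnot(inherits(spec, "grid_spec"), n_layers >= 1)
  if (is.null(cross_corr)) cross_corr <- diag(n_layers)
  cross_corr <- as.matrix(cross_corr)
  if (!isTRUE(all.equal(cross_corr, t(cross_corr), tolerance = 1e-8)))
    stop("cross_corr must be symmetric")
  ev <- eigen(cross_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("cross_corr must be positive-definite")
  if (is.null(layer_names))
    layer_names <- default_layer_names(n_layers)
  stopifnot(length(layer_names) == n_layers)
  if (is.null(nodata_mask))
    nodata_mask <- matrix(FALSE, spec$n_rows, spec$n_cols)

  set.seed(seed)
  Sr <- gauss_smoother(spec$n_rows, corr_length)
  Sc <- gauss_smoother(spec$n_cols, corr_length)
  valid <- !nodata_mask
  fields <- matrix(0, sum(valid), n_layers)
  for (j in seq_len(n_layers)) {
    z <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                spec$n_rows, spec$n_cols)
    sm <- Sr %*% z %*% t(Sc)
    v <- sm[valid]
    fields[, j] <- (v - mean(v)) / stats::sd(v)
  }
  ## whiten: spatially smooth fields carry sizeable sample correlations
  ## (few effective degrees of freedom), so remove them exactly first
  fields <- fields %*% solve(chol(stats::cov(fields)))
  ## cov(F U) = U' cov(F) U = U'U = cross_corr when U = chol(cross_corr)
  mixed <- fields %*% chol(cross_corr)
  layers <- vector("list", n_layers)
  for (j in seq_len(n_layers)) {
    v <- mixed[, j]
    v <- (v - mean(v)) / stats::sd(v)
    m <- matrix(0, spec$n_rows, spec$n_cols)
    m[valid] <- v
    layers[[j]] <- raster_layer(spec, m, nodata_mask, name = layer_names[j])
  }
  predictor_stack(layers, scenario_id = scenario_id)
}

default_layer_names <- function(n) {
  base <- c("bio7", "elev", "bio18", "bio19", "bio3", "bio15", "bio2",
            "bio8", "bio12", "bio15b")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("decoy", seq_len(n - length(base))))
}

gauss_smoother <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- exp(-0.5 * (d / sd)^2)
  w / rowSums(w)
}

#' Known ground-truth suitability model
#'
#' Suitability is a logistic function of standardized predictor values:
#' `p(x) = plogis(intercept + sum(beta * z) + sum(gamma * z^2))` with
#' `gamma <= 0` so responses are flat or unimodal, emulating a species with
#' an ecological optimum at moderate predictor values.
#'
#' @param layer_names predictors the model uses.
#' @param intercept logit-scale intercept.
#' @param linear_coefs per-layer linear coefficients (logit units per SD).
#' @param quad_coefs per-layer quadratic coefficients (<= 0).
#' @return an object of class `true_model`.
#' @export
true_model <- function(layer_names, intercept = 0,
                       linear_coefs = rep(0, length(layer_names)),
                       quad_coefs = rep(0, length(layer_names))) {
  stopifnot(length(linear_coefs) == length(layer_names),
            length(quad_coefs) == length(layer_names))
  if (any(quad_coefs > 0))
    stop("quad_coefs must be <= 0 (unimodal or monotone response)")
  structure(list(layer_names = layer_names, intercept = intercept,
                 linear_coefs = linear_coefs, quad_coefs = quad_coefs),
            class = "true_model")
}

#' Default ground-truth world used throughout the test-bed
#'
#' Four signal layers (bio7, elev, bio18, bio19) with linear effects
#' (1.5, -1.0, 0.8, 0.4) on the logit scale and strong unimodal
#' curvature proportional to each |beta| (factor -6), so a layer's
#' total contribution ranks consistently with its linear effect size and
#' the effect-size ordering stays well-defined.  The intercept is
#' calibrated so the species occupies a restricted, near-binary niche
#' (~10-15% of cells with truth > 0.5, ideal-scorer TSS ~0.75-0.8),
#' mirroring a regionally concentrated species on a continental
#' background whose distribution models clear a TSS = 0.70 inclusion
#' gate.  Decoy layers carry no effect.
#' @export
default_true_model <- function() {
  beta <- c(1.5, -1.0, 0.8, 0.4)
  true_model(layer_names = c("bio7", "elev", "bio18", "bio19"),
             intercept = 5,
             linear_coefs = beta,
             quad_coefs = -6 * abs(beta))
}

#' Evaluate the true suitability surface on a stack
#'
#' Layer values are standardized over the stack's valid cells before the
#' polynomial is applied, so the model's coefficients are scale-free.
#'
#' @param model a [true_model()].
#' @param stack a [predictor_stack()] containing all model layers.
#' @return a probability [raster_layer()] masked wherever any input is.
#' @export
true_suitability <- function(model, stack) {
  missing <- setdiff(model$layer_names, names(stack$layers))
  if (length(missing)) stop("missing layer(s): ", paste(missing, collapse = ", "))
  valid <- !stack$nodata_mask
  eta <- rep(model$intercept, sum(valid))
  for (i in seq_along(model$layer_names)) {
    v <- stack$layers[[model$layer_names[i]]]$values[valid]
    z <- (v - mean(v)) / stats::sd(v)
    eta <- eta + model$linear_coefs[i] * z + model$quad_coefs[i] * z^2
  }
  m <- matrix(0, stack$spec$n_rows, stack$spec$n_cols)
  m[valid] <- stats::plogis(eta)
  raster_layer(stack$spec, m, stack$nodata_mask, name = "truth")
}

#' Contamination specification for synthetic occurrence tables
#'
#' Each count plants records violating exactly one cleaning rule; every
#' planted record carries its intended violation in the `truth_tag` column
#' so cleaning tests have an oracle without information leakage.
#'
#' @param n_missing records lacking coordinates.
#' @param n_coarse records with coordinate precision 0.05 degrees.
#' @param n_old records collected in 1960.
#' @param n_equal records with equal longitude and latitude.
#' @param n_elev records with out-of-range elevation (50 m).
#' @param n_dup duplicate-cell pairs (extra record in an occupied cell).
#' @export
contamination_spec <- function(n_missing = 2, n_coarse = 2, n_old = 2,
                               n_equal = 2, n_elev = 2, n_dup = 2) {
  structure(list(n_missing = n_missing, n_coarse = n_coarse, n_old = n_old,
                 n_equal = n_equal, n_elev = n_elev, n_dup = n_dup),
            class = "contamination_spec")
}

#' Sample presence records from a true suitability surface
#'
#' Presence cells are drawn without replacement with probability
#' proportional to the truth value; each point is placed at the cell
#' center plus a uniform jitter smaller than half a cell, so it stays in
#' its cell.  Clean records get metadata that passes every cleaning rule
#' (precision 0.001 deg, years 1990-2020, elevation 300-2000 m).
#' Contaminated records are appended afterwards and tagged.
#'
#' @param truth a probability [raster_layer()].
#' @param n number of genuine presences.
#' @param seed integer seed.
#' @param contamination a [contamination_spec()] or NULL.
#' @return an [occurrence_table()] with `n + k` records (k contaminated).
#' @export
sample_occurrences <- function(truth, n, seed = 123, contamination = NULL) {
  spec <- truth$spec
  valid <- which(!truth$nodata_mask)
  if (n > length(valid)) stop("n exceeds the number of valid cells")
  set.seed(seed)
  p <- truth$values[valid]
  pick <- sample(valid, n, replace = FALSE, prob = p)
  row <- ((pick - 1L) %% spec$n_rows) + 1L
  col <- ((pick - 1L) %/% spec$n_rows) + 1L
  jit <- function(k) stats::runif(k, -0.45, 0.45) * spec$cell_size
  lon <- cell_center_lon(spec, col) + jit(n)
  lat <- cell_center_lat(spec, row) + jit(n)
  tab <- occurrence_table(id = sprintf("occ%04d", seq_len(n)),
                          lon = lon, lat = lat,
                          precision_deg = 0.001,
                          year = sample(1990:2020, n, replace = TRUE),
                          elevation_m = stats::runif(n, 300, 2000))
  if (is.null(contamination)) return(tab)

  cs <- contamination
  mk <- function(k, tag, ...) {
    if (k == 0) return(NULL)
    args <- list(...)
    base <- list(id = sprintf("bad-%s-%02d", tag, seq_len(k)),
                 lon = stats::runif(k, spec$lon_min + 0.1 * spec$cell_size,
                                    spec$lon_min + (spec$n_cols - 0.1) * spec$cell_size),
                 lat = stats::runif(k, spec$lat_max - (spec$n_rows - 0.1) * spec$cell_size,
                                    spec$lat_max - 0.1 * spec$cell_size),
                 precision_deg = 0.001, year = 2000,
                 elevation_m = 1000, truth_tag = tag)
    base[names(args)] <- args
    do.call(occurrence_table, base)
  }
  bad <- list(
    mk(cs$n_missing, "missing-coords", lat = NA_real_),
    mk(cs$n_coarse, "precision", precision_deg = 0.05),
    mk(cs$n_old, "year", year = 1960L),
    mk(cs$n_equal, "equal-coords",
       lon = 25 + seq_len(max(cs$n_equal, 1)) * 0.01,
       lat = 25 + seq_len(max(cs$n_equal, 1)) * 0.01),
    mk(cs$n_elev, "elevation", elevation_m = 50))
  if (cs$n_dup > 0) {
    src <- tab[seq_len(min(cs$n_dup, nrow(tab))), ]
    ## ids sort after the genuine "occNNNN" ids so the thinning tie rule
    ## drops the planted duplicate, keeping the oracle exact
    dup <- occurrence_table(id = sprintf("zdup-duplicate-cell-%02d", seq_len(nrow(src))),
                            lon = src$lon, lat = src$lat,
                            precision_deg = 0.001, year = 2000,
                            elevation_m = 1000, truth_tag = "duplicate-cell")
    bad <- c(bad, list(dup))
  }
  bad <- bad[!vapply(bad, is.null, logical(1))]
  out <- do.call(rbind, c(list(tab), bad))
  class(out) <- c("occurrence_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Per-layer climate shift defining a future scenario
#'
#' @param scenario_id scenario label.
#' @param shift named numeric vector of per-layer mean shifts (layer units).
#' @param scale named numeric vector of per-layer scale factors.
#'   The terrain layer `"elev"` may not be shifted or rescaled.
#' @export
scenario_delta <- function(scenario_id, shift = numeric(0), scale = numeric(0)) {
  if ("elev" %in% names(shift) && any(shift[["elev"]] != 0))
    stop("the terrain layer 'elev' cannot be shifted across scenarios")
  if ("elev" %in% names(scale) && any(scale[["elev"]] != 1))
    stop("the terrain layer 'elev' cannot be rescaled across scenarios")
  structure(list(scenario_id = scenario_id, shift = shift, scale = scale),
            class = "scenario_delta")
}

#' Apply a scenario delta to a predictor stack
#'
#' Per layer: `value' = (value - mean) * scale + mean + shift`, with the
#' mean taken over valid cells.  Masks and untouched layers (including
#' `"elev"`) are unchanged.
#'
#' @param stack a [predictor_stack()].
#' @param delta a [scenario_delta()].
#' @return a new [predictor_stack()] labelled with the delta's scenario id.
#' @export
apply_scenario <- function(stack, delta) {
  touched <- union(names(delta$shift), names(delta$scale))
  missing <- setdiff(touched, names(stack$layers))
  if (length(missing)) stop("delta names layers not in stack: ",
                            paste(missing, collapse = ", "))
  layers <- stack$layers
  for (nm in touched) {
    l <- layers[[nm]]
    sh <- if (nm %in% names(delta$shift)) delta$shift[[nm]] else 0
    sc <- if (nm %in% names(delta$scale)) delta$scale[[nm]] else 1
    valid <- !l$nodata_mask
    mu <- mean(l$values[valid])
    v <- l$values
    v[valid] <- (v[valid] - mu) * sc + mu + sh
    layers[[nm]] <- raster_layer(l$spec, v, l$nodata_mask, name = nm)
  }
  predictor_stack(layers, scenario_id = delta$scenario_id)
}

#' Default future-scenario deltas for the synthetic world
#'
#' Six scenario-period combinations (three emission pathways x two
#' periods) expressed as increasing mean shifts and mild variance
#' inflation of the climate layers; the terrain layer is untouched.
#' Shift magnitudes (0.4-1.6 SD of the baseline layers) span the range
#' from mild to strong forcing.
#'
#' @param climate_layers layers to perturb (default the bio* signal set).
#' @export
default_scenarios <- function(climate_layers = c("bio7", "bio18", "bio19")) {
  strength <- c("SSP126-2050s" = 0.4, "SSP126-2090s" = 0.7,
                "SSP370-2050s" = 0.8, "SSP370-2090s" = 1.2,
                "SSP585-2050s" = 1.1, "SSP585-2090s" = 1.6)
  lapply(names(strength), function(id) {
    s <- strength[[id]]
    shift <- stats::setNames(s * c(1, -0.5, 0.3)[seq_along(climate_layers)],
                             climate_layers)
    scale <- stats::setNames(rep(1 + 0.1 * s, length(climate_layers)),
                             climate_layers)
    scenario_delta(id, shift = shift, scale = scale)
  })
}
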