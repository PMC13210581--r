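#' Permutation variable importance of the ensemble
#'
#' For each model layer the corresponding column of the pooled presence +
#' pseudo-absence design is permuted (a fresh deterministic sub-seed per
#' layer x permutation), the ensemble re-predicted, and the product-moment
#' correlation with the intact predictions recorded; importance is
#' `1 - mean(correlation)` over `n_perm` permutations.  Degenerate cases
#' (zero-variance predictions) map to importance 0 with a warning.
#'
#' @param ens a calibrated [ensemble_model].
#' @param n_perm permutations per layer (default 10).
#' @param seed master seed.
#' @return data.frame with `layer`, `importance`, `n_permutations`, sorted
#'   by importance descending.
#' @export
permutation_importance <- function(ens, n_perm = 10, seed = 123) {
  pooled <- pooled_dataset(ens)
  X <- pooled$X
  p0 <- predict_ensemble_rows(ens, X)
  const0 <- stats::sd(p0) == 0
  recs <- lapply(ens$layers, function(nm) {
    cors <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      set.seed(derive_seed(seed, "perm", nm, k))
      Xp <- X
      Xp[, nm] <- X[sample(nrow(X)), nm]
      pk <- predict_ensemble_rows(ens, Xp)
      if (const0 || stats::sd(pk) == 0) {
        cors[k] <- 1  # convention: no signal -> importance 0
      } else cors[k] <- stats::cor(p0, pk)
    }
    data.frame(layer = nm, importance = 1 - mean(cors),
               n_permutations = n_perm, stringsAsFactors = FALSE)
  })
  if (const0) warning("intact ensemble predictions are constant; ",
                      "importances set to 0 by convention")
  out <- do.call(rbind, recs)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "layer", "importance", "n_permutations")]
}

#' Evaluation-strip response curve for one predictor
#'
#' The chosen layer is swept over `n_points` equally spaced values across
#' its observed range in the pooled design while every other layer is held
#' at its median; the ensemble prediction (0-1000 scale) is returned per
#' grid point.  A constant column yields a single-point flat curve rather
#' than an error.
#'
#' @param ens a calibrated [ensemble_model].
#' @param layer layer name.
#' @param n_points sweep resolution (default 100).
#' @return data.frame with `value`, `suitability` (0-1000) and
#'   `presence_support` (presence rows in each of `n_points` equal-width
#'   bins, so sparsely supported curve regions are visible).
#' @export
evaluation_strip <- function(ens, layer, n_points = 100) {
  if (!layer %in% ens$layers) stop("unknown layer: ", layer)
  pooled <- pooled_dataset(ens)
  X <- pooled$X
  rng <- range(X[, layer])
  grid <- if (diff(rng) == 0) rng[1]
          else seq(rng[1], rng[2], length.out = n_points)
  med <- apply(X, 2, stats::median)
  Xg <- matrix(rep(med, each = length(grid)), nrow = length(grid),
               dimnames = list(NULL, colnames(X)))
  Xg[, layer] <- grid
  p <- predict_ensemble_rows(ens, Xg)
  pres_vals <- X[pooled$y == 1, layer]
  support <- if (diff(rng) == 0) length(pres_vals)
  else {
    bins <- findInterval(pres_vals, grid, rightmost.closed = TRUE)
    tabulate(pmax(bins, 1L), nbins = length(grid))
  }
  data.frame(value = grid, suitability = round_half_up(1000 * p),
             presence_support = support)
}
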