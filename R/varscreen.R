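#' Build the pooled presence + background screening sample
#'
#' Rows are the presence cells plus `n_background` cells drawn uniformly
#' without replacement from the stack's valid cells; columns are the
#' candidate layers.  Each layer also gets a removal priority used to
#' break collinearity ties: by default its univariate AUC for
#' discriminating presences from background (the computable analogue of
#' "ecological relevance or univariate discrimination"), overridable via
#' `priority`.
#'
#' @param stack a [predictor_stack()].
#' @param presences an [occurrence_table()] validated on the stack.
#' @param n_background background cell count (default 10000).
#' @param seed integer seed.
#' @param priority optional named numeric vector overriding the default
#'   per-layer priority.
#' @return an object of class `screening_sample` with elements `matrix`,
#'   `layer_names`, `labels` (1 presence / 0 background), `priority`.
#' @export
build_screening_sample <- function(stack, presences, n_background = 10000,
                                   seed = 123, priority = NULL) {
  spec <- stack$spec
  pc <- presence_cells(presences, spec)
  pres_idx <- (pc$col - 1L) * spec$n_rows + pc$row
  valid_idx <- which(!stack$nodata_mask)
  if (any(stack$nodata_mask[pres_idx])) stop("presences on masked cells")
  if (n_background > length(valid_idx))
    stop("n_background exceeds the number of valid cells")
  set.seed(seed)
  bg_idx <- if (n_background > 0) sample(valid_idx, n_background) else integer(0)
  idx <- c(pres_idx, bg_idx)
  mat <- vapply(stack$layers, function(l) l$values[idx], numeric(length(idx)))
  mat <- matrix(mat, nrow = length(idx),
                dimnames = list(NULL, names(stack$layers)))
  labels <- c(rep(1L, length(pres_idx)), rep(0L, length(bg_idx)))
  if (is.null(priority)) {
    if (n_background > 0) {
      priority <- vapply(colnames(mat), function(nm) {
        a <- roc_auc(mat[, nm], labels)
        max(a, 1 - a)  # discrimination regardless of direction
      }, numeric(1))
    } else priority <- stats::setNames(rep(0.5, ncol(mat)), colnames(mat))
  }
  stopifnot(all(colnames(mat) %in% names(priority)))
  structure(list(matrix = mat, layer_names = colnames(mat), labels = labels,
                 priority = priority[colnames(mat)], seed = seed),
            class = "screening_sample")
}

#' Pairwise-correlation filter
#'
#' Offending pairs (|r| >= cutoff) are processed in descending |r|; for
#' each pair whose members both survive so far, the lower-priority member
#' is removed (priority ties broken by removing the later name in sort
#' order).  Repeats until no remaining pair offends.
#'
#' @param sample a [screening_sample()] (or plain numeric matrix).
#' @param cutoff absolute-correlation threshold (default 0.80).
#' @param priority needed only when `sample` is a bare matrix.
#' @return character vector of retained layer names; the removal trace is
#'   attached as attribute `"removed"`.
#' @export
correlation_filter <- function(sample, cutoff = 0.80, priority = NULL) {
  if (inherits(sample, "screening_sample")) {
    mat <- sample$matrix; priority <- sample$priority
  } else {
    mat <- as.matrix(sample)
    if (is.null(priority))
      priority <- stats::setNames(rep(0, ncol(mat)), colnames(mat))
  }
  if (ncol(mat) < 2) stop("need at least two layers")
  cm <- stats::cor(mat, use = "pairwise.complete.obs")
  alive <- colnames(mat)
  removed <- character(0)
  repeat {
    sub <- abs(cm[alive, alive, drop = FALSE])
    diag(sub) <- 0
    if (all(sub < cutoff, na.rm = TRUE)) break
    hit <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- alive[hit[1]]; b <- alive[hit[2]]
    drop_nm <- if (priority[[a]] < priority[[b]]) a
               else if (priority[[b]] < priority[[a]]) b
               else sort(c(a, b))[2]
    alive <- setdiff(alive, drop_nm)
    removed <- c(removed, drop_nm)
    if (length(alive) < 2) break
  }
  structure(alive, removed = removed)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of column j on all other columns plus an intercept.  Exact
#' collinearity is reported as `Inf`.
#'
#' @param mat numeric matrix (rows = cells, columns = layers), >= 2 cols.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(mat) {
  mat <- as.matrix(mat)
  p <- ncol(mat)
  if (p < 2) stop("need at least two columns")
  if (nrow(mat) < p + 1) stop("fewer rows than columns + 1")
  out <- stats::setNames(numeric(p), colnames(mat))
  for (j in seq_len(p)) {
    y <- mat[, j]
    X <- cbind(1, mat[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    tss <- sum((y - mean(y))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss == 0) 0 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Stepwise VIF elimination
#'
#' Repeatedly removes the layer with the largest VIF while that VIF
#' exceeds the threshold (ties broken by lower priority, then by later
#' name in sort order).
#'
#' @param sample a [screening_sample()], or a numeric matrix.
#' @param threshold VIF threshold (default 10).
#' @param priority needed only for a bare matrix.
#' @param layers optionally restrict to a subset of layer names (e.g. the
#'   survivors of [correlation_filter()]).
#' @return retained layer names, with the ordered removal trace attached
#'   as attribute `"removed"`.
#' @export
vif_stepwise <- function(sample, threshold = 10, priority = NULL,
                         layers = NULL) {
  if (inherits(sample, "screening_sample")) {
    mat <- sample$matrix; priority <- sample$priority
  } else {
    mat <- as.matrix(sample)
    if (is.null(priority))
      priority <- stats::setNames(rep(0, ncol(mat)), colnames(mat))
  }
  alive <- layers %||% colnames(mat)
  removed <- character(0)
  while (length(alive) >= 2) {
    v <- vif(mat[, alive, drop = FALSE])
    vmax <- max(v)
    if (vmax <= threshold) break
    worst <- names(v)[v == vmax]
    if (length(worst) > 1) {
      pr <- priority[worst]
      worst <- worst[pr == min(pr)]
      worst <- sort(worst)[length(worst)]
    }
    alive <- setdiff(alive, worst)
    removed <- c(removed, worst)
  }
  structure(alive, removed = removed)
}

#' Two-step collinearity screening
#'
#' Correlation filter first, then stepwise VIF elimination on the
#' survivors, mirroring the standard "pairwise r then iterative VIF"
#' protocol.
#'
#' @param sample a [screening_sample()].
#' @param r_cutoff pairwise |r| threshold (default 0.80).
#' @param vif_threshold VIF threshold (default 10).
#' @return list with `retained`, `removed_by_correlation`,
#'   `removed_by_vif`, `correlation`, `priority`.
#' @export
screen_predictors <- function(sample, r_cutoff = 0.80, vif_threshold = 10) {
  step1 <- correlation_filter(sample, cutoff = r_cutoff)
  step2 <- vif_stepwise(sample, threshold = vif_threshold,
                        layers = as.character(step1))
  list(retained = as.character(step2),
       removed_by_correlation = attr(step1, "removed"),
       removed_by_vif = attr(step2, "removed"),
       correlation = stats::cor(sample$matrix),
       priority = sample$priority)
}
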