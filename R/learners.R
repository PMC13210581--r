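#' Define a probabilistic base learner
#'
#' The contract every learner must satisfy: `fit(X, y, w, seed)` returns an
#' opaque fitted state; `predict(state, X)` returns finite probabilities in
#' `[0, 1]`; refitting with identical inputs and seed reproduces
#' predictions.  `X` arrives already standardized by the calibration-set
#' mean/SD, so learners need no scaling of their own.
#'
#' @param name learner label.
#' @param fit function(X, y, w, seed) -> state.
#' @param predict function(state, X) -> numeric probabilities.
#' @export
base_learner <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "base_learner")
}

quad_expand <- function(X) {
  X2 <- X^2
  colnames(X2) <- paste0(colnames(X), "_sq")
  cbind(X, X2)
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

#' Weighted logistic regression with quadratic terms
#'
#' Matches the generative family of the synthetic truth (second-order
#' polynomial logit), the classical GLM workhorse of SDM ensembles.
#' @export
learner_glm_quad <- function() {
  base_learner("glm_quad",
    fit = function(X, y, w, seed) {
      d <- as.data.frame(quad_expand(X))
      d$.y <- y
      ## quasibinomial: identical fit to binomial, no non-integer-weight noise
      stats::glm(.y ~ ., data = d, family = stats::quasibinomial("logit"),
                 weights = w)
    },
    predict = function(state, X) {
      clamp01(stats::predict(state, newdata = as.data.frame(quad_expand(X)),
                             type = "response"))
    })
}

#' Ridge-penalised logistic regression (MaxEnt-style stand-in)
#'
#' Quadratic feature expansion with an L2 penalty at a small fixed lambda;
#' deterministic (no internal cross-validation).
#' @param lambda ridge penalty (default 0.01).
#' @export
learner_ridge <- function(lambda = 0.01) {
  force(lambda)
  base_learner("ridge",
    fit = function(X, y, w, seed) {
      glmnet::glmnet(quad_expand(X), y, family = "binomial", alpha = 0,
                     weights = w, lambda = c(1, 0.1, lambda),
                     standardize = FALSE)
    },
    predict = function(state, X) {
      clamp01(stats::predict(state, newx = quad_expand(X), s = lambda,
                             type = "response"))
    })
  }

#' Generalized additive model with cubic regression spline smooths
#'
#' One low-rank smooth per predictor (k = 5, `bs = "cr"`) keeps both
#' fitting and prediction fast on large pseudo-absence designs while
#' capturing unimodal responses.
#' @export
learner_gam <- function() {
  base_learner("gam",
    fit = function(X, y, w, seed) {
      d <- as.data.frame(X)
      vars <- colnames(d)
      d$.y <- y
      fml <- stats::as.formula(paste(".y ~",
        paste(sprintf("s(%s, k = 5, bs = \"cr\")", vars), collapse = " + ")))
      mgcv::gam(fml, data = d, family = stats::quasibinomial("logit"),
                weights = w, method = "GCV.Cp")
    },
    predict = function(state, X) {
      clamp01(stats::predict(state, newdata = as.data.frame(X),
                             type = "response"))
    })
}

#' Weighted Gaussian linear discriminant (FDA-style stand-in)
#'
#' Closed-form discriminant: weighted class means, pooled weighted
#' covariance, equal effective priors (the prevalence weights already
#' balance the classes), posterior through the logistic of the linear
#' discriminant score.
#' @export
learner_fda <- function() {
  base_learner("fda",
    fit = function(X, y, w, seed) {
      wmean <- function(M, wt) colSums(M * wt) / sum(wt)
      w1 <- w[y == 1]; w0 <- w[y == 0]
      m1 <- wmean(X[y == 1, , drop = FALSE], w1)
      m0 <- wmean(X[y == 0, , drop = FALSE], w0)
      ctr <- X
      ctr[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2, m1)
      ctr[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2, m0)
      S <- crossprod(ctr * sqrt(w)) / sum(w)
      S <- S + diag(1e-8, ncol(X))
      a <- solve(S, m1 - m0)
      b <- -0.5 * sum((m1 + m0) * a) + log(sum(w1) / sum(w0))
      list(a = a, b = b)
    },
    predict = function(state, X) {
      clamp01(stats::plogis(drop(X %*% state$a) + state$b))
    })
}

#' Rectangular range-envelope scorer (SRE-style stand-in)
#'
#' Predicts 1 inside the per-variable central presence quantile box
#' (default the 2.5%-97.5% envelope), 0 outside.
#' @param quantile tail mass trimmed per side (default 0.025).
#' @export
learner_sre <- function(quantile = 0.025) {
  force(quantile)
  base_learner("sre",
    fit = function(X, y, w, seed) {
      P <- X[y == 1, , drop = FALSE]
      list(lo = apply(P, 2, stats::quantile, probs = quantile, names = FALSE),
           hi = apply(P, 2, stats::quantile, probs = 1 - quantile, names = FALSE))
    },
    predict = function(state, X) {
      inside <- rep(TRUE, nrow(X))
      for (j in seq_len(ncol(X)))
        inside <- inside & X[, j] >= state$lo[j] & X[, j] <= state$hi[j]
      as.numeric(inside)
    })
}

#' Constant-probability test double
#' @param p the constant prediction.
#' @export
learner_constant <- function(p = 0.5) {
  force(p)
  base_learner("constant",
    fit = function(X, y, w, seed) list(p = p),
    predict = function(state, X) rep(state$p, nrow(X)))
}

#' Default learner set
#'
#' Five contract implementations drawn from what the environment provides:
#' quadratic GLM, ridge logistic, GAM, Gaussian discriminant, and the
#' range envelope.
#' @export
default_learners <- function() {
  list(learner_glm_quad(), learner_ridge(), learner_gam(),
       learner_fda(), learner_sre())
}
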