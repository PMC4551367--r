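# Penalized multivariate Granger causality: ridge, lasso and elastic net on
# the stacked VAR design, with cross-validated penalty selection. The ridge
# solver is the workhorse of CGC-2SPR's first step, so it is written around a
# thin SVD of X whose cost scales with m (the number of stacked equations),
# not with the n*p predictors -- essential when n >> T.

#' Penalty configuration for regularized GC fits
#'
#' @param method One of `"ridge"`, `"lasso"`, `"enet"`.
#' @param lambda_grid Ordered positive penalty grid for cross-validation.
#'   Default: 25 log-spaced points over 1e-4 ... 1e2.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param enet_mixing Elastic-net mixing `alpha` in \[0, 1\] (1 = lasso,
#'   0 = ridge); used only for `method = "enet"`.
#' @param shuffle If `TRUE`, folds are random given a seed; the default is
#'   contiguous blocks of time-equations, which respects serial dependence.
#' @param rule Penalty selection rule: `"1se"` (default) picks the largest
#'   penalty whose CV error is within one standard error of the minimum --
#'   the usual parsimony rule, and the only stable choice when the error
#'   curve is flat over decades of the grid (the typical n >> T situation);
#'   `"min"` picks the argmin (ties to the larger penalty).
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(method = c("ridge", "lasso", "enet"),
                           lambda_grid = 10^seq(-4, 2, length.out = 25),
                           cv_folds = 5, enet_mixing = 0.5, shuffle = FALSE,
                           rule = c("1se", "min")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0))
    gn_stop("lambda_grid must be a nonempty vector of positive values",
            "gn_parameter_error")
  if (cv_folds < 2) gn_stop("cv_folds must be >= 2", "gn_parameter_error")
  if (method == "enet" && (enet_mixing < 0 || enet_mixing > 1))
    gn_stop("enet_mixing must be in [0, 1]", "gn_parameter_error")
  structure(list(method = method, lambda_grid = sort(lambda_grid),
                 cv_folds = as.integer(cv_folds), enet_mixing = enet_mixing,
                 shuffle = shuffle, rule = rule),
            class = "penalty_config")
}

# Thin SVD of the design, reused across lambdas and by the CGC-2SPR closed
# form.
#' @noRd
design_svd <- function(X) {
  sv <- svd(X)
  list(u = sv$u, d = sv$d, v = sv$v)
}

# Ridge coefficients from a precomputed SVD: B = V diag(d/(d^2+l)) U'Y.
# Exact for any m, n*p: components of X'Y outside the row space are zero.
#' @noRd
ridge_coef_svd <- function(sv, Y, lambda1) {
  sv$v %*% ((sv$d / (sv$d^2 + lambda1)) * crossprod(sv$u, Y))
}

#' Ridge-regularized VAR estimation
#'
#' Minimizes `1/2 ||Y - XB||_F^2 + 1/2 lambda1 ||B||_F^2`, whose closed form
#' is `B = (X'X + lambda1 I)^{-1} X'Y`. Always defined, including the
#' under-determined regime `m < n*p`; computed through the SVD of X so cost
#' scales with `m`.
#'
#' @param design A `var_design` from [build_design()].
#' @param lambda1 Penalty weight, > 0.
#' @return A `gc_fit` list (`B`, `residuals`, `rss`, `lambda1`).
#' @export
ridge_fit <- function(design, lambda1) {
  if (!is.numeric(lambda1) || lambda1 <= 0)
    gn_stop("lambda1 must be > 0", "gn_parameter_error")
  sv <- design_svd(design$X)
  B <- ridge_coef_svd(sv, design$Y, lambda1)
  dimnames(B) <- list(colnames(design$X), colnames(design$Y))
  finish_fit(B, design$X, design$Y, method = "ridge", lambda1 = lambda1)
}

# Shared glmnet-backed L1/elastic-net solve; each target gene is an
# independent column regression. Our objective 1/2||y-Xb||^2 + lambda1*P(b)
# maps to glmnet's (1/2m)||y-Xb||^2 + lambda*P(b) via lambda = lambda1/m.
#' @noRd
glmnet_fit <- function(design, lambda1, alpha, method) {
  if (!is.numeric(lambda1) || lambda1 <= 0)
    gn_stop("lambda1 must be > 0", "gn_parameter_error")
  X <- design$X; Y <- design$Y
  m <- nrow(X)
  lam <- lambda1 / m
  # a descending path from the per-target lambda_max warm-starts the
  # coordinate descent; in the under-determined regime the convergence
  # threshold is relaxed (at near-zero penalty the interpolating solution is
  # not unique and tight convergence is unattainable and meaningless)
  thresh <- if (ncol(X) > m) 1e-7 else 1e-9
  B <- matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  for (j in seq_len(ncol(Y))) {
    lmax <- max(max(abs(crossprod(X, Y[, j]))) / m, 4 * lam)
    path <- exp(seq(log(lmax), log(lam), length.out = 20))
    fit <- glmnet::glmnet(X, Y[, j], family = "gaussian", alpha = alpha,
                          lambda = path, standardize = FALSE,
                          intercept = FALSE, thresh = thresh)
    cf <- coef(fit, s = lam, exact = FALSE)
    B[, j] <- as.numeric(cf)[-1]
  }
  finish_fit(B, X, Y, method = method, lambda1 = lambda1)
}

#' Lasso-regularized VAR estimation
#'
#' Minimizes `1/2 ||Y - XB||_F^2 + lambda1 ||B||_1`, each target gene solved
#' independently by glmnet coordinate descent.
#'
#' @inheritParams ridge_fit
#' @return A `gc_fit` list.
#' @export
lasso_fit <- function(design, lambda1) {
  glmnet_fit(design, lambda1, alpha = 1, method = "lasso")
}

#' Elastic-net-regularized VAR estimation
#'
#' Minimizes `1/2 ||Y - XB||_F^2 + lambda1 [ (1-alpha)/2 ||B||_F^2 +
#' alpha ||B||_1 ]`, the standard elastic-net mixing form.
#'
#' @inheritParams ridge_fit
#' @param enet_mixing Mixing parameter `alpha` in \[0, 1\].
#' @return A `gc_fit` list.
#' @export
enet_fit <- function(design, lambda1, enet_mixing = 0.5) {
  glmnet_fit(design, lambda1, alpha = enet_mixing, method = "enet")
}

#' Fit at a given penalty according to a penalty configuration
#'
#' @param design A `var_design`.
#' @param cfg A `penalty_config`.
#' @param lambda1 Penalty weight.
#' @return A `gc_fit`.
#' @export
penalized_fit <- function(design, cfg, lambda1) {
  switch(cfg$method,
         ridge = ridge_fit(design, lambda1),
         lasso = lasso_fit(design, lambda1),
         enet = enet_fit(design, lambda1, cfg$enet_mixing))
}

#' Cross-validated penalty selection
#'
#' Partitions the `m` stacked time-equations into `cv_folds` folds
#' (contiguous blocks by default, to respect serial dependence; shuffled
#' folds behind `cfg$shuffle`) and computes the mean held-out squared
#' prediction error for every penalty in the grid. The returned penalty
#' follows `cfg$rule`: the one-standard-error parsimony rule by default, or
#' the plain minimizer (ties to the larger penalty).
#'
#' @param expr Expression matrix (genes x time).
#' @param p Model order.
#' @param cfg A `penalty_config`.
#' @param seed Integer seed (used only when `cfg$shuffle` is `TRUE`; the
#'   contiguous-block default is fully deterministic).
#' @return A list with `best_lambda1` and `cv_errors` (data frame of
#'   `lambda`, `mse`, `se` -- the standard error of the fold means).
#' @export
cross_validate <- function(expr, p, cfg, seed = 1L) {
  design <- build_design(expr, p)
  m <- design$m
  if (cfg$cv_folds > m)
    gn_stop(sprintf("cv_folds=%d exceeds m=%d stacked equations",
                    cfg$cv_folds, m), "gn_parameter_error")
  grid <- cfg$lambda_grid
  K <- cfg$cv_folds
  fold <- rep(seq_len(K), each = ceiling(m / K))[seq_len(m)]
  if (cfg$shuffle)
    fold <- withr::with_seed(seed, sample(fold))
  fold_mse <- matrix(NA_real_, K, length(grid))
  for (k in seq_len(K)) {
    tr <- fold != k; te <- !tr
    Xtr <- design$X[tr, , drop = FALSE]; Ytr <- design$Y[tr, , drop = FALSE]
    Xte <- design$X[te, , drop = FALSE]; Yte <- design$Y[te, , drop = FALSE]
    if (cfg$method == "ridge") {
      sv <- design_svd(Xtr)
      UtY <- crossprod(sv$u, Ytr)
      XteV <- Xte %*% sv$v
      for (g in seq_along(grid)) {
        pred <- XteV %*% ((sv$d / (sv$d^2 + grid[g])) * UtY)
        fold_mse[k, g] <- mean((Yte - pred)^2)
      }
    } else {
      alpha <- if (cfg$method == "lasso") 1 else cfg$enet_mixing
      lam_path <- sort(grid, decreasing = TRUE) / nrow(Xtr)
      sse <- numeric(length(grid))
      for (j in seq_len(ncol(Ytr))) {
        fit <- glmnet::glmnet(Xtr, Ytr[, j], family = "gaussian",
                              alpha = alpha, lambda = lam_path,
                              standardize = FALSE, intercept = FALSE,
                              thresh = 1e-7)
        pred <- predict(fit, newx = Xte, s = lam_path)
        err <- colSums((Yte[, j] - pred)^2)
        sse <- sse + rev(err)   # back to ascending grid order
      }
      fold_mse[k, ] <- sse / length(Yte)
    }
  }
  mse <- colMeans(fold_mse)
  se <- apply(fold_mse, 2, sd) / sqrt(K)
  imin <- max(which(mse == min(mse)))
  best <- if (cfg$rule == "1se")
    grid[max(which(mse <= mse[imin] + se[imin]))]
  else
    grid[imin]
  list(best_lambda1 = best,
       cv_errors = data.frame(lambda = grid, mse = mse, se = se))
}
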