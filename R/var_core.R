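# Lagged VAR design construction and ordinary least squares, shared by every
# Granger-causality method in the package.
#
# Conventions (used by all downstream modules):
#   * expression matrices are genes x time; the design transposes internally
#     so that stacked equations are time-in-rows;
#   * Y is m x n with m = T - p, row t holding the observation vector at time
#     p + t;
#   * X is m x (n*p) in lag-major blocks ordered lag 1, lag 2, ..., lag p
#     (most recent lag first); within a block genes appear in gene_ids order;
#   * the coefficient matrix B is (n*p) x n, row block i holding the lag-i
#     coefficients, so B[(i-1)*n + g, h] is the effect of gene g at lag i on
#     gene h.

#' Build the stacked VAR(p) design matrices
#'
#' Stacks the regression equations of a vector autoregression of order `p`
#' into a single multivariate least-squares problem `Y = X B + E`.
#'
#' @param expr Numeric matrix, genes in rows, time in columns, gene ids as
#'   row names.
#' @param p Model order (maximum lag), `1 <= p <= T - 1`.
#' @return A `var_design` list with elements `Y` (m x n), `X` (m x n*p),
#'   `p`, `m` and `gene_ids`.
#' @export
build_design <- function(expr, p) {
  check_expression(expr)
  Tn <- ncol(expr); n <- nrow(expr)
  p <- as.integer(p)
  if (p < 1 || p >= Tn)
    gn_stop(sprintf("invalid model order p=%d for T=%d (need 1 <= p <= T-1)",
                    p, Tn), "gn_order_error")
  m <- Tn - p
  Zt <- t(expr)                      # time x genes
  Y <- Zt[(p + 1):Tn, , drop = FALSE]
  X <- matrix(0, m, n * p)
  for (lag in seq_len(p))
    X[, ((lag - 1) * n + 1):(lag * n)] <- Zt[(p + 1 - lag):(Tn - lag), , drop = FALSE]
  colnames(Y) <- rownames(expr)
  colnames(X) <- paste0(rep(rownames(expr), p), "_lag",
                        rep(seq_len(p), each = n))
  structure(list(Y = Y, X = X, p = p, m = m, gene_ids = rownames(expr)),
            class = "var_design")
}

#' Ordinary least squares estimation of a VAR design
#'
#' Solves `min_B ||Y - XB||_F^2` through the normal equations. Requires a
#' full-column-rank design (`m >= n*p`, i.e. `T >= (n+1)p`); rank deficiency
#' is an error here by design -- the regularized fits ([ridge_fit()],
#' [lasso_fit()]) handle the under-determined n >> T regime.
#'
#' @param design A `var_design` from [build_design()].
#' @return A `gc_fit` list with `B` ((n*p) x n coefficients), `residuals`
#'   (m x n) and `rss` (per-target residual sum of squares).
#' @export
ols_estimate <- function(design) {
  X <- design$X; Y <- design$Y
  if (nrow(X) < ncol(X))
    gn_stop(sprintf(paste0("design is under-determined (m=%d rows < %d ",
                           "predictors); T >= (n+1)p is violated -- use a ",
                           "regularized fit (ridge_fit/lasso_fit)"),
                    nrow(X), ncol(X)), "gn_singular_error")
  G <- crossprod(X)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R))
    gn_stop(paste0("X'X is singular; use a regularized fit ",
                   "(ridge_fit/lasso_fit)"), "gn_singular_error")
  B <- backsolve(R, forwardsolve(t(R), crossprod(X, Y)))
  dimnames(B) <- list(colnames(X), colnames(Y))
  finish_fit(B, X, Y, method = "ols")
}

#' @noRd
finish_fit <- function(B, X, Y, method, lambda1 = NA_real_) {
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  structure(list(B = B, residuals = resid, rss = rss, method = method,
                 lambda1 = lambda1),
            class = "gc_fit")
}

#' Per-target RSS of the OLS fit excluding one gene's lags
#'
#' Refits the full multivariate OLS model with every lag of `excluded_gene`
#' removed from the predictor set, and returns the residual sum of squares of
#' each remaining target. Comparing these against the full-model RSS is the
#' basis of conditional Granger-causality F-statistics (valid only when the
#' reduced design is still over-determined).
#'
#' @param expr Expression matrix (genes x time).
#' @param p Model order.
#' @param excluded_gene Gene id to leave out of the predictors.
#' @return Named numeric vector of RSS values for the remaining targets.
#' @export
rss_for_subset <- function(expr, p, excluded_gene) {
  check_expression(expr)
  if (!excluded_gene %in% rownames(expr))
    gn_stop(sprintf("gene '%s' not present", excluded_gene), "gn_format_error")
  sub <- expr[setdiff(rownames(expr), excluded_gene), , drop = FALSE]
  ols_estimate(build_design(sub, p))$rss
}
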