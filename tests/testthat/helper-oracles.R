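# Shared fixtures and independent oracles used across the suite.

# simulate a zero-noise VAR(p) trajectory from a known coefficient matrix
# (lag-major (n*p) x n layout, as used by the package)
simulate_var <- function(B, n, p, T, noise = 0, init = NULL) {
  x <- matrix(0, n, T)
  x[, seq_len(p)] <- if (is.null(init)) rnorm(n * p) else init
  for (t in (p + 1):T) {
    acc <- numeric(n)
    for (lag in seq_len(p)) {
      Bl <- B[((lag - 1) * n + 1):(lag * n), , drop = FALSE]
      acc <- acc + as.numeric(crossprod(Bl, x[, t - lag]))
    }
    x[, t] <- acc + if (noise > 0) rnorm(n, 0, noise) else 0
  }
  rownames(x) <- sprintf("g%03d", seq_len(n))
  x
}

# numerical minimizer of the prior-target ridge objective
#   1/2||Y-XB||_F^2 + 1/2 l1 ||B - l2 W||_F^2
# by quasi-Newton descent on the vectorized coefficients; independent of the
# package's closed-form solver
optim_prior_ridge <- function(X, Y, lambda1, lambda2 = 0, W = NULL) {
  q <- ncol(X); n <- ncol(Y)
  if (is.null(W)) W <- matrix(0, q, n)
  fn <- function(b) {
    B <- matrix(b, q, n)
    R <- Y - X %*% B
    0.5 * sum(R^2) + 0.5 * lambda1 * sum((B - lambda2 * W)^2)
  }
  gr <- function(b) {
    B <- matrix(b, q, n)
    as.numeric(crossprod(X, X %*% B - Y) + lambda1 * (B - lambda2 * W))
  }
  o <- optim(rep(0, q * n), fn, gr, method = "L-BFGS-B",
             control = list(maxit = 2000, factr = 1e3))
  list(B = matrix(o$par, q, n), value = o$value, fn = fn)
}

# quick expression fixture: n white-noise genes
white_noise_expr <- function(n, T, ids = sprintf("g%03d", seq_len(n))) {
  matrix(rnorm(n * T), n, T, dimnames = list(ids, NULL))
}

# a tiny planted-parent fixture: gene "child" driven by "pa" at lag 1
planted_pair_expr <- function(T, coef = 0.9, noise = 1e-3) {
  pa <- as.numeric(arima.sim(list(ar = 0.5), T))
  child <- numeric(T)
  child[1] <- rnorm(1)
  for (t in 2:T) child[t] <- coef * pa[t - 1] + rnorm(1, 0, noise)
  rbind(pa = pa, child = child)
}

ranking_key <- function(r) paste(r$source, r$target)

# hand-built ranking (sorted by the package's own tie rules)
new_test_ranking <- function(source, target, score, p_value = NULL) {
  grangernet:::new_ranking(source, target, score, p_value = p_value)
}
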