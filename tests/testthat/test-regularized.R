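test_that("ridge matches OLS as the penalty vanishes and shrinks to zero", {
  withr::local_seed(7)
  z <- simulate_var(matrix(c(0.5, 0.2, -0.1, 0.4), 2, 2), 2, 1, 40,
                    noise = 0.3)
  d <- build_design(z, 1)
  ols <- ols_estimate(d)
  expect_lt(max(abs(ridge_fit(d, 1e-8)$B - ols$B)), 1e-6)
  expect_lt(max(abs(ridge_fit(d, 1e12)$B)), 1e-6)
  expect_error(ridge_fit(d, 0), class = "gn_parameter_error")
})

test_that("ridge satisfies its stationarity condition on n >> T designs", {
  withr::local_seed(8)
  z <- white_noise_expr(20, 12)      # m = 10 rows, 40 predictors
  d <- build_design(z, 2)
  for (lam in c(0.01, 1)) {
    fit <- ridge_fit(d, lam)
    g <- crossprod(d$X, d$X %*% fit$B - d$Y) + lam * fit$B
    expect_lt(max(abs(g)), 1e-6 * max(1, max(abs(crossprod(d$X, d$Y)))))
  }
  # Frobenius norm shrinks monotonically in lambda
  norms <- sapply(10^seq(-3, 3, by = 1), function(l) sqrt(sum(ridge_fit(d, l)$B^2)))
  expect_true(all(diff(norms) < 0))
})

test_that("ridge closed form agrees with an iterative convex solver", {
  withr::local_seed(9)
  z <- white_noise_expr(10, 8)       # under-determined: m = 6, 20 predictors
  d <- build_design(z, 2)
  sub <- d
  sub$Y <- d$Y[, 1:4]
  fit <- ridge_fit(sub, 0.5)
  o <- optim_prior_ridge(sub$X, sub$Y, 0.5)
  expect_lt(abs(o$fn(as.numeric(fit$B)) - o$value), 1e-6 * max(1, o$value))
  expect_lte(o$fn(as.numeric(fit$B)), o$value + 1e-6)
})

test_that("ridge primal formula and SVD route agree in the dual regime", {
  withr::local_seed(10)
  z <- white_noise_expr(15, 10)      # m = 8, 30 predictors
  d <- build_design(z, 2)
  lam <- 0.3
  direct <- solve(crossprod(d$X) + lam * diag(ncol(d$X)), crossprod(d$X, d$Y))
  expect_lt(max(abs(ridge_fit(d, lam)$B - direct)), 1e-8)
})

test_that("lasso has an exact dead zone and approaches OLS for tiny penalties", {
  withr::local_seed(11)
  z <- simulate_var(matrix(c(0.5, 0.2, -0.1, 0.4), 2, 2), 2, 1, 60,
                    noise = 0.3)
  d <- build_design(z, 1)
  lmax <- max(abs(crossprod(d$X, d$Y[, 1])))
  fit <- lasso_fit(d, lmax * 1.01)
  expect_identical(unname(fit$B[, 1]), c(0, 0))
  ols <- ols_estimate(d)
  expect_lt(max(abs(lasso_fit(d, 1e-6)$B - ols$B)), 1e-4)
})

test_that("lasso recovers a planted sparse parent set at the CV penalty", {
  withr::local_seed(12)
  n_dec <- 100; T <- 50
  decoys <- white_noise_expr(n_dec, T, sprintf("d%03d", seq_len(n_dec)))
  pa <- white_noise_expr(3, T, c("pa1", "pa2", "pa3"))
  child <- numeric(T); child[1] <- rnorm(1)
  for (t in 2:T) child[t] <- 0.9 * pa[1, t - 1] - 0.8 * pa[2, t - 1] +
      0.7 * pa[3, t - 1] + rnorm(1, 0, 0.05)
  expr <- rbind(decoys, pa, child = child)
  # the plain CV minimizer is the right instrument here: the one-SE rule
  # averages over the 103 pure-noise decoy targets and over-shrinks the one
  # signal-bearing column
  cv <- cross_validate(expr, 1, penalty_config("lasso", rule = "min"), seed = 1)
  fit <- lasso_fit(build_design(expr, 1), cv$best_lambda1)
  top3 <- names(sort(abs(fit$B[, "child"]), decreasing = TRUE))[1:3]
  expect_setequal(top3, c("pa1_lag1", "pa2_lag1", "pa3_lag1"))
})

test_that("cross-validation picks shrinkage extremes in the limiting regimes", {
  withr::local_seed(13)
  grid <- 10^seq(-4, 2, length.out = 10)
  # pure noise: maximal shrinkage wins
  noise <- white_noise_expr(6, 24)
  cvn <- cross_validate(noise, 2, penalty_config("ridge", grid), seed = 1)
  expect_equal(cvn$best_lambda1, max(grid))
  # noiseless well-determined VAR (a non-decaying rotation, so the signal
  # persists across all folds): no penalty wins
  th <- 0.4
  z <- simulate_var(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                    2, 1, 60)
  cv0 <- cross_validate(z, 1, penalty_config("ridge", grid), seed = 1)
  expect_equal(cv0$best_lambda1, min(grid))
  # machinery accepts and can return the grid value 0.01
  cv01 <- cross_validate(noise, 2, penalty_config("ridge", 0.01), seed = 1)
  expect_equal(cv01$best_lambda1, 0.01)
  expect_error(penalty_config("ridge", numeric(0)), class = "gn_parameter_error")
  expect_error(cross_validate(noise, 2, penalty_config("ridge", grid, cv_folds = 40)),
               class = "gn_parameter_error")
})

test_that("elastic net interpolates between ridge and lasso behavior", {
  withr::local_seed(14)
  z <- white_noise_expr(8, 20)
  d <- build_design(z, 2)
  fe <- enet_fit(d, 0.5, enet_mixing = 0.5)
  fl <- lasso_fit(d, 0.5)
  # enet at alpha = 1 is lasso
  fe1 <- enet_fit(d, 0.5, enet_mixing = 1)
  expect_lt(max(abs(fe1$B - fl$B)), 1e-6)
  # lasso is never denser than the half-mixed enet at equal lambda1
  expect_lte(sum(fl$B != 0), sum(fe$B != 0) + 2)
})
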