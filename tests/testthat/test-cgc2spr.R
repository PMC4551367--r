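test_that("prior matrix is tiled, mapped and filtered as documented", {
  ids <- c("a", "b", "c", "d")
  pr <- edge_list(c("a", "b", "x"), c("b", "c", "a"), c(2, 4, 9))
  expect_message(pw <- build_prior_matrix(pr, ids, 3, "linear"), "dropped 1")
  expect_equal(dim(pw$W), c(12L, 4L))
  # linear mapping: divide by max in-universe weight
  expect_equal(pw$W["a_lag1", "b"], 0.5)
  expect_equal(pw$W["b_lag1", "c"], 1)
  # p identical vertical copies
  expect_identical(unname(pw$W[1:4, ]), unname(pw$W[5:8, ]))
  expect_identical(unname(pw$W[1:4, ]), unname(pw$W[9:12, ]))

  pwb <- suppressMessages(build_prior_matrix(pr, ids, 2, "binary"))
  expect_setequal(unique(as.numeric(pwb$W)), c(0, 1))
  expect_equal(sum(pwb$W != 0), 2 * 2)  # 2 surviving edges x p copies

  empty <- edge_list(character(0), character(0), numeric(0))
  pe <- build_prior_matrix(empty, ids, 2)
  expect_equal(max(abs(pe$W)), 0)
  expect_warning(build_prior_matrix(edge_list("q", "r", 1), ids, 2),
                 "outside the gene universe")
})

test_that("prior matrix reaches benchmark scale with the documented shape", {
  cfg <- simulation_config(seed = 4)
  gold <- generate_network(cfg)
  prior <- generate_prior_clique(gold)
  pw <- build_prior_matrix(prior, gold$nodes, 3, "binary")
  expect_equal(dim(pw$W), c(3000L, 1000L))
  expect_equal(sum(pw$W != 0), 3L * nrow(prior))
})

test_that("sign adjustment flips signs entrywise and preserves magnitudes", {
  ids <- c("a", "b")
  pr <- edge_list(c("a", "b"), c("b", "a"), 1)
  pw <- build_prior_matrix(pr, ids, 2, "binary")
  Bstar <- matrix(c(1, -2, 3, 0.5, -1, 2, 0, -3), 4, 2)
  s <- sign_adjust(pw, Bstar)
  expect_true(s$signed)
  expect_equal(abs(s$W), abs(pw$W), ignore_attr = TRUE)
  expect_equal(s$W[2, 1], -1)          # negative B* flips the entry
  expect_equal(s$W[1, 2], -1)          # B*[1, 2] < 0 flips a_lag1 -> b too
  # all-positive B* leaves W unchanged; zero entries keep positive sign
  pw2 <- build_prior_matrix(pr, ids, 2, "binary")
  s2 <- sign_adjust(pw2, abs(Bstar))
  expect_equal(s2$W, pw2$W)
  expect_error(sign_adjust(s2, abs(Bstar)), class = "gn_parameter_error")
  expect_error(sign_adjust(build_prior_matrix(pr, ids, 2), Bstar[1:3, ]),
               class = "gn_shape_error")
})

test_that("lambda2 = 0 reduces the two-step fit to ordinary ridge exactly", {
  withr::local_seed(21)
  z <- white_noise_expr(6, 15)
  d <- build_design(z, 2)
  pr <- edge_list("g001", "g002", 1)
  out <- fit_cgc_2spr(d, pr, spr_config(0.2, 0, 2))
  expect_identical(out$result$B, ridge_fit(d, 0.2)$B)

  # empty prior with auto lambda2 degrades to ridge with a warning
  empty <- edge_list(character(0), character(0), numeric(0))
  expect_warning(out2 <- fit_cgc_2spr(d, empty, spr_config(0.2, "auto", 2)),
                 "ordinary ridge")
  expect_identical(out2$result$B, ridge_fit(d, 0.2)$B)
  expect_equal(out2$resolved_lambda2, 0)
})

test_that("a dominant penalty pulls the solution onto the signed prior", {
  withr::local_seed(22)
  z <- white_noise_expr(5, 14)
  d <- build_design(z, 2)
  pr <- edge_list(c("g001", "g002", "g004"), c("g002", "g003", "g005"), 1)
  out <- fit_cgc_2spr(d, pr, spr_config(1e8, 0.37, 2))
  target <- 0.37 * out$signed_W$W
  expect_lt(max(abs(out$result$B - target)), 1e-4 * max(abs(target), 1))
})

test_that("the closed form minimizes the prior-target objective", {
  withr::local_seed(23)
  for (rep in 1:3) {
    z <- white_noise_expr(8, 12)          # m = 10, 16 predictors
    d <- build_design(z, 2)
    sub <- d; sub$Y <- d$Y[, 1:5]
    lam1 <- 0.7; lam2 <- 0.3
    W <- matrix(rbinom(16 * 5, 1, 0.2) * sign(rnorm(16 * 5)), 16, 5)
    # closed form via the package path on a matching handmade prior:
    Bhat <- solve(crossprod(sub$X) + lam1 * diag(16),
                  crossprod(sub$X, sub$Y) + lam1 * lam2 * W)
    o <- optim_prior_ridge(sub$X, sub$Y, lam1, lam2, W)
    expect_lt(abs(o$fn(as.numeric(Bhat)) - o$value), 1e-6 * max(1, o$value))
    # gradient vanishes at the closed form
    g <- crossprod(sub$X, sub$X %*% Bhat - sub$Y) + lam1 * (Bhat - lam2 * W)
    expect_lt(max(abs(g)), 1e-8 * max(1, max(abs(crossprod(sub$X, sub$Y)))))
  }
})

test_that("auto lambda2 balances the data and prior scales", {
  withr::local_seed(24)
  z <- white_noise_expr(4, 16)
  d <- build_design(z, 2)
  pr <- edge_list(c("g001", "g002"), c("g002", "g003"), c(0.4, 0.8))
  out <- fit_cgc_2spr(d, pr, spr_config(0.5, "auto", 2))
  expect_equal(out$resolved_lambda2,
               max(abs(out$b_star)) / max(abs(out$signed_W$W)))
})

test_that("gene relabeling permutes the fit equivariantly", {
  withr::local_seed(25)
  z <- white_noise_expr(5, 14)
  pr <- edge_list(c("g001", "g003"), c("g002", "g005"), 1)
  cfg <- spr_config(0.3, "auto", 2)
  r1 <- fit_cgc_2spr(build_design(z, 2), pr, cfg)
  rk1 <- rank_from_coefficients(r1$result, rownames(z))
  perm <- c(4, 2, 5, 1, 3)
  z2 <- z[perm, ]
  r2 <- fit_cgc_2spr(build_design(z2, 2), pr, cfg)
  rk2 <- rank_from_coefficients(r2$result, rownames(z2))
  m1 <- rk1$score[order(ranking_key(rk1))]
  m2 <- rk2$score[order(ranking_key(rk2))]
  expect_equal(m1, m2, tolerance = 1e-10)
})
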