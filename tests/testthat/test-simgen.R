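test_that("a single fully activated module has the canonical 1->3->9 shape", {
  cfg <- simulation_config(module_repeats = 1, perturbation_edges = 0,
                           activation_rate = 1, total_nodes = 13, seed = 3)
  gold <- generate_network(cfg)
  expect_length(gold$nodes, 13)
  expect_equal(nrow(gold$edges), 12)
  expect_equal(sum(gold$roles == "master"), 1)
  expect_equal(sum(gold$roles == "effector"), 12)
  expect_true(all(gold$edges$lag %in% 1:3))
  expect_false(any(gold$edges$source == gold$edges$target))
  # masters have no incoming edges
  master <- names(gold$roles)[gold$roles == "master"]
  expect_false(master %in% gold$edges$target)
})

test_that("full activation without perturbation keeps every base module", {
  cfg <- simulation_config(module_repeats = 60, perturbation_edges = 0,
                           activation_rate = 1, total_nodes = 780, seed = 5)
  gold <- generate_network(cfg)
  expect_length(gold$nodes, 780)        # 13 x 60 base nodes all survive
  expect_equal(nrow(gold$edges), 720)   # 12 edges per module
  expect_equal(sum(gold$roles == "master"), 60)
})

test_that("the default configuration matches the benchmark conditions", {
  gold <- generate_network(simulation_config(seed = 2))
  expect_length(gold$nodes, 1000)
  expect_gt(nrow(gold$edges), 700)
  expect_lt(nrow(gold$edges), 1500)
  # isolated padding genes touch no golden-standard edge
  iso <- names(gold$roles)[gold$roles == "isolated"]
  expect_false(any(gold$edges$source %in% iso | gold$edges$target %in% iso))
  # every retained effector keeps at least one retained parent
  eff <- names(gold$roles)[gold$roles == "effector"]
  expect_true(all(eff %in% gold$edges$target))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(module_repeats = 5, perturbation_edges = 20,
                           total_nodes = 80, seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$gold$edges, d2$gold$edges)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$prior, d2$prior)
  d3 <- simulate_dataset(simulation_config(module_repeats = 5,
                                           perturbation_edges = 20,
                                           total_nodes = 80, seed = 12))
  expect_false(identical(d1$expr, d3$expr))
})

test_that("the noiseless oscillator is period-12 and the printed form explodes", {
  x <- withr::with_seed(1, ar2_master_series(40, d = 1, noise_sigma = 0))
  expect_lt(max(abs(x[14:40] - x[2:28])), 1e-9)
  y <- withr::with_seed(1, ar2_master_series(40, d = 1, noise_sigma = 0,
                                             form = "printed"))
  expect_gt(max(abs(y)), 1e6)
})

test_that("expression has the configured shape and is exactly z-scored", {
  cfg <- simulation_config(seed = 6)
  gold <- generate_network(cfg)
  x <- generate_expression(gold, cfg)
  expect_equal(dim(x), c(1000L, 20L))
  expect_lt(max(abs(rowMeans(x))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(x^2)) - 1)), 1e-12)
})

test_that("noiseless effectors are exact linear functions of their parents", {
  cfg <- simulation_config(module_repeats = 4, perturbation_edges = 10,
                           activation_rate = 1, total_nodes = 60,
                           noise_sigma = 0, seed = 8)
  gold <- generate_network(cfg)
  x <- generate_expression(gold, cfg, normalize = FALSE)
  L <- cfg$max_lag
  eff <- names(gold$roles)[gold$roles == "effector"]
  for (k in head(eff, 5)) {
    pe <- gold$edges[gold$edges$target == k, ]
    for (t in (L + 1):cfg$T) {
      pred <- sum(pe$coefficient * x[cbind(match(pe$source, gold$nodes),
                                           t - pe$lag)])
      expect_lt(abs(x[k, t] - pred), 1e-9)
    }
  }
})

test_that("the clique prior has the documented accuracy structure", {
  # one fully surviving module: 156 ordered prior pairs, 12 true
  cfg <- simulation_config(module_repeats = 1, perturbation_edges = 0,
                           activation_rate = 1, total_nodes = 13, seed = 3)
  gold <- generate_network(cfg)
  prior <- generate_prior_clique(gold)
  expect_equal(nrow(prior), 13 * 12)
  expect_equal(prior_accuracy(prior, gold), 12 / 156)

  # a module reduced to one survivor contributes no prior edges
  gold1 <- gold
  gold1$module[] <- NA_integer_
  gold1$module[gold$nodes[1]] <- 1L
  expect_equal(nrow(generate_prior_clique(gold1)), 0)

  # the full prior never contains cross-module pairs
  cfgd <- simulation_config(seed = 9)
  gd <- generate_network(cfgd)
  pr <- generate_prior_clique(gd)
  mod <- gd$module
  expect_true(all(mod[pr$source] == mod[pr$target]))
})
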