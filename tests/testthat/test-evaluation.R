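test_that("coefficient ranking aggregates lags and breaks ties stably", {
  # single nonzero entry dominates
  ids <- c("u", "v")
  B <- matrix(0, 4, 2, dimnames = list(c("u_l1", "v_l1", "u_l2", "v_l2"), ids))
  B["v_l2", "u"] <- -0.7
  r <- rank_from_coefficients(B, ids)
  expect_equal(r$source[1], "v"); expect_equal(r$target[1], "u")
  expect_equal(r$score[1], 0.7)

  # max aggregation over lags {0.2, -0.9} -> 0.9; sum -> 1.1; l2
  B2 <- matrix(0, 4, 2, dimnames = list(NULL, ids))
  B2[2, 1] <- 0.2; B2[4, 1] <- -0.9
  expect_equal(rank_from_coefficients(B2, ids, "max")$score[1], 0.9)
  expect_equal(rank_from_coefficients(B2, ids, "sum")$score[1], 1.1)
  expect_equal(rank_from_coefficients(B2, ids, "l2")$score[1],
               sqrt(0.2^2 + 0.9^2))

  # equal scores fall back to lexicographic (source, target) order
  B3 <- matrix(1, 3, 3)
  r3 <- rank_from_coefficients(B3, c("c", "a", "b"))
  expect_identical(paste(r3$source, r3$target)[1:3], c("a b", "a c", "b a"))
  r3b <- rank_from_coefficients(B3, c("c", "a", "b"))
  expect_identical(r3, r3b)
  # the autoregressive diagonal is excluded
  expect_equal(nrow(r3), 6)
})

test_that("PRC behaves correctly at the extremes and under random ranking", {
  gold <- data.frame(source = c("a", "b"), target = c("b", "c"))
  perfect <- new_test_ranking(c("a", "b", "c", "c"), c("b", "c", "a", "b"),
                              c(4, 3, 2, 1))
  pc <- prc(perfect, gold)
  expect_equal(pc$auprc, 1)
  expect_true(all(pc$points$precision[1:2] == 1))

  none <- new_test_ranking(c("c", "c"), c("a", "b"), c(2, 1))
  expect_warning(p0 <- prc(none, gold), "no golden-standard")
  expect_equal(p0$auprc, 0)

  # random rankings give precision ~ prevalence at every depth
  withr::local_seed(51)
  ids <- letters[1:8]
  univ <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  univ <- univ[univ$source != univ$target, ]
  g8 <- univ[sample(nrow(univ), 7), ]
  final_prec <- replicate(100, {
    sh <- univ[sample(nrow(univ)), ]
    r <- new_test_ranking(sh$source, sh$target, rev(seq_len(nrow(sh))))
    tail(prc(r, g8)$points$precision, 1)
  })
  expect_equal(mean(final_prec), 7 / nrow(univ), tolerance = 1e-10)
})

test_that("F1 at k = |gold| collapses to precision = recall", {
  gold <- data.frame(source = c("a", "b", "c", "d"),
                     target = c("b", "c", "d", "a"))
  exact <- new_test_ranking(gold$source, gold$target, 4:1)
  ev <- f1_at_k(exact, gold, 4)
  expect_equal(ev$f1, 1); expect_equal(ev$precision, ev$recall)

  disjoint <- new_test_ranking(c("b", "c", "d", "a"), c("a", "b", "c", "d"), 4:1)
  expect_equal(f1_at_k(disjoint, gold, 4)$f1, 0)

  half <- new_test_ranking(c("a", "b", "x", "y"), c("b", "c", "y", "x"), 4:1)
  evh <- f1_at_k(half, gold, 4)
  expect_equal(evh$precision, 0.5)
  expect_equal(evh$recall, 0.5)
  expect_equal(evh$f1, 0.5)
})

test_that("short rankings are padded over the universe with a warning", {
  gold <- data.frame(source = "a", target = "b")
  short <- new_test_ranking("a", "c", 1)
  expect_warning(ev <- f1_at_k(short, gold, 5, universe = c("a", "b", "c")),
                 "padding")
  # padded lexicographic pairs are a->b, b->a, b->c, c->a: contains the gold
  expect_equal(ev$hits, 1)
  expect_equal(ev$precision, 1 / 5)
})

test_that("top-k overlap is monotone and bounded by |gold|", {
  withr::local_seed(52)
  ids <- letters[1:6]
  gold <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "d"))
  sc <- white_noise_expr(6, 10, ids)
  r <- pgc_all_pairs(sc, 1)
  ks <- c(1, 5, 10, 20, 30)
  ov <- sapply(ks, function(k) topk_overlap(r, gold, k))
  expect_true(all(diff(ov) >= 0))
  expect_lte(max(ov), 3)
  expect_equal(topk_overlap(r, gold, nrow(r)), 3)   # gold within full list
  expect_equal(topk_overlap(r, data.frame(source = character(0),
                                          target = character(0)), 5), 0L)
})

test_that("p-value distribution reports separate planted from null scenarios", {
  withr::local_seed(53)
  null_r <- new_test_ranking(rep("a", 2000), paste0("t", 1:2000),
                             rep(1, 2000), p_value = runif(2000))
  rep1 <- pvalue_distribution_report(list(null = null_r, same = null_r))
  expect_equal(rep1[1, -1], rep1[2, -1], ignore_attr = TRUE)
  expect_equal(rep1$median_log10_p[1], log10(0.5), tolerance = 0.05)

  strong <- new_test_ranking(rep("a", 200), paste0("s", 1:200), rep(1, 200),
                             p_value = runif(200, 0, 1e-3))
  rep2 <- pvalue_distribution_report(list(gold = strong, random = null_r))
  expect_lt(rep2$median_log10_p[rep2$scenario == "gold"],
            rep2$median_log10_p[rep2$scenario == "random"])
  expect_error(pvalue_distribution_report(list(new_test_ranking("a", "b", 1))),
               class = "gn_parameter_error")
})
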