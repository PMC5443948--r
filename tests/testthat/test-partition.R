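test_that("chance-expected accuracy follows the size formula", {
  expect_equal(expected_accuracy(c(50, 50))$expected_accuracy, 0.5)
  expect_equal(expected_accuracy(100)$expected_accuracy, 1)
  res <- expected_accuracy(c(80, 50, 30, 25, 20))
  expect_equal(res$expected_accuracy, 10825 / 42025)
  expect_equal(res$expected_correct, 10825 / 205, tolerance = 1e-12)
  # equal sizes give exactly 1/k
  for (k in 2:6) {
    expect_equal(expected_accuracy(rep(7, k))$expected_accuracy, 1 / k)
  }
})

test_that("equal sizes minimise the chance null for fixed total and k", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    sizes <- sample(1:40, k, replace = TRUE)
    N <- sum(sizes)
    unequal <- expected_accuracy(sizes)$expected_accuracy
    expect_gte(unequal + 1e-12, 1 / k)   # Cauchy-Schwarz bound
  }
})

test_that("Wald CI half-widths reproduce the published values", {
  expect_equal(round(binomial_wald_ci(169, 205), 2), 5.21)
  expect_equal(round(binomial_wald_ci(120, 219), 2), 6.59)
  expect_equal(round(binomial_wald_ci(216, 339), 2), 5.12)
  expect_equal(binomial_wald_ci(46, 46), 0)
  expect_equal(binomial_wald_ci(0, 50), 0)
  expect_error(binomial_wald_ci(5, 0), "positive")
})

test_that("Fisher's exact test matches exhaustive hypergeometric enumeration", {
  tables <- list(c(1, 9, 11, 3), c(5, 5, 5, 5), c(0, 10, 10, 0),
                 c(3, 1, 1, 3), c(12, 2, 7, 8), c(2, 0, 0, 2))
  for (tb in tables) {
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 fisher_enum(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-9)
  }
  # identical rows carry no signal
  expect_equal(fisher_exact_2x2(7, 3, 7, 3), 1)
  # an all-zero margin is defined as p = 1
  expect_equal(fisher_exact_2x2(0, 0, 5, 5), 1)
  # the published parasitized-warbler contrast is overwhelming
  expect_lt(fisher_exact_2x2(44, 161, 169, 36), 0.001)
})

test_that("ranked Welch test matches the hand-computed formula on a 6+6 fixture", {
  a <- c(95, 97, 99, 100, 92, 96)
  b <- c(80, 85, 96, 88, 90, 79)
  ours <- ranked_welch(a, b)
  manual <- welch_on_ranks_manual(a, b)
  expect_equal(ours$statistic, manual$statistic, tolerance = 1e-12)
  expect_equal(ours$df, manual$df, tolerance = 1e-12)
  expect_equal(ours$p_value, manual$p, tolerance = 1e-12)
  # identical samples: no signal
  same <- ranked_welch(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  # complete separation at n = 5 per side is significant
  sep <- ranked_welch(6:10, 1:5)
  expect_lt(sep$p_value, 0.05)
  # both samples constant and equal: statistic 0, p = 1
  flat <- ranked_welch(rep(5, 4), rep(5, 4))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("summary-table arithmetic reproduces its own identities", {
  counts <- tibble::tibble(n = 100L, expected_correct = 25L,
                           observed_correct = 25L)
  res <- summary_table_arithmetic(counts)
  expect_equal(res$improvement_pct, 0)
  expect_equal(res$fisher_p, 1)
  counts2 <- tibble::tibble(n = 200L, expected_correct = 50L,
                            observed_correct = 180L)
  res2 <- summary_table_arithmetic(counts2)
  expect_equal(res2$accuracy_pct, 90)
  expect_equal(res2$improvement_pct, 90 - 25)
  expect_lt(res2$fisher_p, 0.001)
})

test_that("groupwise analysis fills every summary column coherently", {
  tbl <- generate_study(warbler_community_spec(seed = 6))
  pp <- preprocess_phenotypes(tbl)
  res <- groupwise_analysis(pp$data, "parasitized", "dfa")
  expect_equal(res$n, sum(pp$data$role == "host"))
  expect_equal(res$accuracy_pct, 100 * res$observed_correct / res$n)
  expect_equal(res$improvement_pct,
               res$accuracy_pct - res$expected_accuracy_pct)
  expect_equal(res$ci_halfwidth_pct,
               binomial_wald_ci(res$observed_correct, res$n))
  # a zero-separation group improves about nothing over chance
  flat <- generate_community(random_community_spec(
    3, 0, clutches_parasitized = 40, separation_parasitized = 0, seed = 7))
  res0 <- groupwise_analysis(flat, "parasitized", "dfa")
  expect_lt(abs(res0$improvement_pct), 15)
})

test_that("pairwise analysis enumerates all pairs with the right chance null", {
  tbl <- generate_study(warbler_community_spec(seed = 8))
  pp <- preprocess_phenotypes(tbl)
  pw <- pairwise_analysis(pp$data, "parasitized")
  expect_equal(nrow(pw), choose(5, 2))
  expect_equal(pw$expected_pct,
               100 * (pw$n_a^2 + pw$n_b^2) / (pw$n_a + pw$n_b)^2)
  # equal-size pair: expected exactly 50
  eq <- generate_community(random_community_spec(
    2, 0, clutches_parasitized = 30, separation_parasitized = 0, seed = 9))
  pw_eq <- pairwise_analysis(eq, "parasitized")
  expect_equal(pw_eq$expected_pct, 50)
  # identical distributions: observed near chance
  expect_lt(abs(pw_eq$observed_pct - pw_eq$expected_pct), 20)
})

test_that("cross-group comparison detects a real accuracy contrast", {
  tbl <- generate_study(warbler_community_spec(seed = 10))
  pp <- preprocess_phenotypes(tbl)
  g1 <- groupwise_analysis(pp$data, "parasitized", "dfa")
  g2 <- groupwise_analysis(pp$data, "unparasitized", "dfa")
  cmp <- compare_group_accuracy(g1, g2)
  expect_gt(g1$accuracy_pct, g2$accuracy_pct)
  expect_lt(cmp$p_value[cmp$comparison == "observed"], 0.05)
})
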