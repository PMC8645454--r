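test_that("identical per-cluster tables give a zero interaction statistic", {
  deaths <- rbind(c(20, 20), c(20, 20))
  totals <- rbind(c(100, 100), c(100, 100))
  d <- expand_2x2x2(deaths, totals)
  h <- interaction_lrt(d$y, d$w, d$cluster)
  expect_equal(h$lrt_statistic, 0, tolerance = 1e-6)
  expect_equal(h$p_value, 1, tolerance = 1e-6)
  expect_false(h$significant)
  expect_equal(h$odds_ratios$odds_ratio, c(1, 1), tolerance = 1e-10)
})

test_that("interaction LRT matches an independent likelihood-maximisation oracle", {
  # cluster 1: treated 10/100 vs control 20/100; cluster 2: 30/100 vs 15/100
  deaths <- rbind(c(20, 10), c(15, 30)) # [cluster, arm(control, treated)]
  totals <- matrix(100, 2, 2)
  d <- expand_2x2x2(deaths, totals)
  h <- interaction_lrt(d$y, d$w, d$cluster)
  oracle <- lrt_oracle_2x2x2(deaths, totals)
  expect_equal(h$lrt_statistic, oracle$statistic, tolerance = 1e-5)
  expect_equal(h$p_value, oracle$p_value, tolerance = 1e-6)
  expect_equal(h$df, 1L)
  ors <- h$odds_ratios$odds_ratio
  expect_equal(ors[1], (10 * 80) / (90 * 20), tolerance = 1e-10) # 0.444
  expect_equal(ors[2], (30 * 85) / (70 * 15), tolerance = 1e-10) # 2.429
})

test_that("the interaction test is invariant to relabelling and recodes ORs under arm swap", {
  set.seed(1)
  n <- 400
  cl <- rep(1:2, each = n / 2)
  w <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * w * (cl == 2) - 0.4 * w * (cl == 1)))
  h1 <- interaction_lrt(y, w, cl)
  h2 <- interaction_lrt(y, w, 3 - cl)        # relabel clusters
  expect_equal(h1$lrt_statistic, h2$lrt_statistic, tolerance = 1e-8)
  h3 <- interaction_lrt(y, 1 - w, cl)        # swap arms
  expect_equal(h1$lrt_statistic, h3$lrt_statistic, tolerance = 1e-6)
  expect_equal(h1$odds_ratios$odds_ratio, 1 / h3$odds_ratios$odds_ratio,
               tolerance = 1e-8)
})

test_that("inestimable designs are flagged, never silently fitted", {
  y <- c(0, 1, 0, 1, 1, 0)
  w <- c(0, 0, 0, 1, 1, 1)
  cl <- c(1, 1, 1, 2, 2, 2) # cluster 1 has no treated subjects
  h <- interaction_lrt(y, w, cl)
  expect_false(h$estimable)
  expect_match(h$reason, "empty cell")
  expect_false(h$significant)
  h1 <- interaction_lrt(y, w, rep(1, 6))
  expect_false(h1$estimable)
})

test_that("per-cluster odds ratios follow the cross-product formula with Wald CI", {
  d <- expand_2x2x2(rbind(c(20, 10), c(20, 10)), matrix(100, 2, 2))
  or <- per_cluster_or(d$y, d$w, d$cluster)
  expect_equal(or$odds_ratio[1], 0.4444, tolerance = 1e-3)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 20 + 1 / 80)
  expect_equal(or$ci_low[1], exp(log(or$odds_ratio[1]) - 1.96 * se),
               tolerance = 1e-10)
  expect_false(any(or$corrected))
  # zero cell: continuity-corrected, finite, flagged
  y <- c(rep(0, 10), rep(1, 5), rep(0, 5))
  w <- c(rep(1, 10), rep(0, 10))
  orz <- per_cluster_or(y, w, rep(1, 20))
  expect_true(orz$corrected)
  expect_true(is.finite(orz$odds_ratio))
  # one arm absent
  orna <- per_cluster_or(c(0, 1, 0), c(1, 1, 1), rep(1, 3))
  expect_false(orna$estimable)
  expect_true(is.na(orna$odds_ratio))
})

test_that("mortality chi-squared matches the hand formula and the z^2 identity", {
  lab <- rep(1:2, each = 100)
  y <- c(rep(1, 20), rep(0, 80), rep(1, 45), rep(0, 55))
  res <- mortality_chisq(y, lab)
  O <- table(lab, y)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
  expect_equal(res$df, 1)
  # K = 2 equals the squared two-proportion z statistic
  p1 <- 0.20; p2 <- 0.45; pp <- (20 + 45) / 200
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(res$statistic, z^2, tolerance = 1e-10)
  # equal death rates: statistic ~ 0
  y_eq <- rep(c(rep(1, 30), rep(0, 70)), 2)
  expect_equal(mortality_chisq(y_eq, lab)$statistic, 0, tolerance = 1e-10)
  expect_error(mortality_chisq(y, rep(1, 200)), "2 clusters")
})

test_that("variable importance isolates the defining feature and sums to one", {
  set.seed(2)
  n <- 500
  X <- matrix(rnorm(8 * n), n, dimnames = list(NULL, paste0("f", 1:8)))
  labels <- 1L + (X[, 3] > 0)
  vi <- variable_importance(X, labels, seed = 3)
  expect_equal(sum(vi$gain_share), 1, tolerance = 1e-8)
  expect_gt(vi$gain_share[vi$feature == "f3"], 0.9)
  expect_equal(sort(vi$rank), 1:8)
  expect_error(variable_importance(X, rep(1, n)), "at least 2")
})

test_that("random labels spread importance near the uniform share", {
  set.seed(4)
  n <- 600
  p <- 10
  X <- matrix(rnorm(p * n), n, dimnames = list(NULL, paste0("f", 1:p)))
  shares <- replicate(5, {
    labels <- sample(1:2, n, replace = TRUE)
    variable_importance(X, labels, nrounds = 50,
                        seed = sample.int(1e6, 1))$gain_share
  })
  expect_lt(max(rowMeans(shares)), 3 / p)
})
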