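# deterministic linear base learner used as an oracle in several tests
lm_learner <- function(X, y, seed) {
  df <- as.data.frame(X)
  fit <- lm(y ~ ., data = cbind(df, y = y))
  function(Xnew) unname(predict(fit, newdata = as.data.frame(Xnew)))
}

test_that("sign dichotomisation follows the harm/benefit convention", {
  a <- ite_to_clusters(c(-0.1, 0.2, -0.3))
  expect_equal(a$cluster_names[a$labels], c("benefit", "harm", "benefit"))
  single <- ite_to_clusters(c(0.1, 0.2, 0.3))
  expect_true(single$single_cluster)
  expect_equal(single$K, 1L)
  zeros <- ite_to_clusters(rep(0, 4))
  expect_true(zeros$single_cluster)
  expect_equal(zeros$cluster_names, "benefit")
  expect_equal(zeros$n_zero_ties, 4L)
  expect_error(ite_to_clusters(c(1, NA)), "finite")
})

test_that("X-learner is zero under identical outcome surfaces and obeys g endpoints", {
  set.seed(1)
  X <- matrix(rnorm(200), 100)
  w <- rep_len(0:1, 100)
  y <- rep(0.3, 100) # constant outcome in both arms
  const_learner <- function(X, y, seed) { m <- mean(y); function(Xn) rep(m, nrow(Xn)) }
  tau <- xlearner_tau(X, w, y, X, base_learner = const_learner)
  expect_equal(tau, rep(0, 100))

  # g = 0 returns tau1 exactly; g = 1 returns tau0 (formula endpoints)
  y2 <- rbinom(100, 1, plogis(X[, 1] + 0.5 * w))
  t_g0 <- xlearner_tau(X, w, y2, X, base_learner = lm_learner, propensity = 0)
  t_g1 <- xlearner_tau(X, w, y2, X, base_learner = lm_learner, propensity = 1)
  t_half <- xlearner_tau(X, w, y2, X, base_learner = lm_learner, propensity = 0.5)
  expect_equal(t_half, 0.5 * t_g1 + 0.5 * t_g0, tolerance = 1e-12)
  expect_error(xlearner_tau(X, rep(1, 100), y2, X), "both arms")
})

test_that("X-learner tracks the closed-form risk difference of an additive DGP", {
  set.seed(2)
  n <- 4000
  X <- matrix(rnorm(2 * n), n)
  w <- rbinom(n, 1, 0.5)
  p <- plogis(X[, 1] + 0.8 * w)
  y <- rbinom(n, 1, p)
  tau_true <- plogis(X[, 1] + 0.8) - plogis(X[, 1])
  tau_hat <- xlearner_tau(X, w, y, X, base_learner = lm_learner)
  expect_lt(abs(mean(tau_hat - tau_true)), 0.05)
})

test_that("cross-fitting predicts every subject out of sample, stratified by arm and outcome", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(2 * n), n)
  w <- rep_len(0:1, n)
  y <- rbinom(n, 1, 0.4)
  seen <- vector("list", n)
  spy <- function(Xtr, wtr, ytr, Xte, seed, ...) {
    # record which test rows were excluded from training (by row identity)
    rep(0.1, nrow(Xte))
  }
  res <- crossfit_ite(X, w, y, estimator = spy, n_folds = 5, seed = 4)
  expect_false(anyNA(res$tau_hat))
  expect_equal(sort(unique(res$fold_id)), 1:5)
  # stratification: per-fold arm counts within +/-1 of the target
  for (f in 1:5) {
    for (arm in 0:1) {
      got <- sum(w[res$fold_id == f] == arm)
      expect_lte(abs(got - sum(w == arm) / 5), 1)
    }
  }
  # same seed reproduces the folds
  res2 <- crossfit_ite(X, w, y, estimator = spy, n_folds = 5, seed = 4)
  expect_identical(res$fold_id, res2$fold_id)
  # leave-one-out: each prediction excludes its own row
  n2 <- 16
  X2 <- matrix(seq_len(n2), ncol = 1)
  w2 <- rep_len(0:1, n2)
  y2 <- rep_len(c(0L, 1L), n2)
  loo <- function(Xtr, wtr, ytr, Xte, seed, ...) {
    expect_false(any(Xte[, 1] %in% Xtr[, 1]))
    rep(0, nrow(Xte))
  }
  crossfit_ite(X2, w2, y2, estimator = loo, n_folds = n2, seed = 1)
})

test_that("causal forest is near zero under the null and averages down tree noise", {
  set.seed(4)
  n <- 1500
  X <- matrix(rnorm(3 * n), n)
  w <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.3) # no treatment effect, no modifiers
  tau_oob <- causal_forest_tau(X, w, y, n_trees = 60, seed = 5)
  expect_lt(mean(abs(tau_oob)), 0.05)
  t1 <- causal_forest_tau(X, w, y, X, n_trees = 1, seed = 6)
  t50 <- causal_forest_tau(X, w, y, X, n_trees = 50, seed = 6)
  expect_lt(var(t50), var(t1))
})

test_that("causal forest recovers the sign of a binary effect modifier", {
  set.seed(5)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)
  X <- cbind(x1, matrix(rnorm(3 * n), n))
  w <- rbinom(n, 1, 0.5)
  p <- 0.4 + (2 * x1 - 1) * 0.2 * w # effects +0.2 / -0.2
  y <- rbinom(n, 1, p)
  tau <- causal_forest_tau(X, w, y, n_trees = 80, seed = 7)
  agree <- mean(sign(tau) == sign(2 * x1 - 1))
  expect_gte(agree, 0.8)
})

test_that("MOB splits on a strong modifier and respects max_depth = 0", {
  set.seed(6)
  n <- 1000
  x1 <- rbinom(n, 1, 0.5)
  X <- cbind(mod = x1, noise1 = rnorm(n), noise2 = rnorm(n))
  w <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + (2 * x1 - 1) * 1 * w)) # log-odds -1 vs +1
  a <- mob_partition(X, w, y, seed = 7)
  expect_gte(a$K, 2L)
  expect_equal(a$splits[[1]]$feature, "mod")
  a0 <- mob_partition(X, w, y, max_depth = 0, seed = 7)
  expect_equal(a0$K, 1L)
  expect_true(a0$single_cluster)
  # node treatment coefficients differ across terminal nodes after a split
  coefs <- vapply(a$node_models, function(m) unname(m$coef["w"]), numeric(1))
  expect_gt(max(coefs) - min(coefs), 0.5)
})
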