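test_that("K = 1 fit equals the closed-form Gaussian MLE", {
  set.seed(1)
  X <- matrix(rnorm(300, mean = c(2, -1), sd = c(1, 3)), 150, 2, byrow = TRUE)
  m <- lca_fit(X, 1, n_starts = 2, seed = 1)
  expect_equal(drop(m$means), colMeans(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  v_mle <- colMeans(sweep(X, 2, colMeans(X))^2) # denominator n
  expect_equal(drop(m$variances), v_mle, tolerance = 1e-6, ignore_attr = TRUE)
  ll_closed <- sum(vapply(1:2, function(j)
    sum(dnorm(X[, j], colMeans(X)[j], sqrt(v_mle[j]), log = TRUE)), numeric(1)))
  expect_equal(m$log_likelihood, ll_closed, tolerance = 1e-6)
})

test_that("EM recovers a separated two-component mixture", {
  set.seed(2)
  z <- rbinom(1000, 1, 0.4)
  X <- matrix(rnorm(1000, mean = ifelse(z == 1, 3, -3)), ncol = 1)
  m <- lca_fit(X, 2, n_starts = 10, seed = 3)
  mu <- sort(drop(m$means))
  expect_lt(abs(mu[1] - (-3)), 0.2)
  expect_lt(abs(mu[2] - 3), 0.2)
  expect_lt(abs(min(m$weights) - 0.4), 0.05)
  expect_true(all(diff(m$ll_trace) > -1e-8))          # EM monotonicity
  expect_equal(rowSums(m$posteriors), rep(1, 1000), tolerance = 1e-8)
  expect_gt(m$relative_entropy, 0.8)                   # crisp classes
})

test_that("mixed binary indicators enter the likelihood correctly", {
  set.seed(3)
  z <- rep(1:2, each = 300)
  X <- cbind(rnorm(600, ifelse(z == 1, -2, 2)),
             rbinom(600, 1, ifelse(z == 1, 0.9, 0.1)))
  m <- lca_fit(X, 2, types = c("continuous", "binary"), n_starts = 10, seed = 4)
  a <- lca_assignment(m)
  expect_gt(ari(a$labels, z), 0.9)
  p <- sort(drop(m$probs))
  expect_lt(abs(p[1] - 0.1), 0.06)
  expect_lt(abs(p[2] - 0.9), 0.06)
})

test_that("the EM solution matches mclust on diagonal Gaussian data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust)) # Mclust needs its namespace attached
  set.seed(5)
  z <- rep(1:2, each = 250)
  X <- cbind(rnorm(500, ifelse(z == 1, 0, 4)), rnorm(500, ifelse(z == 1, 0, -4)))
  ours <- lca_fit(X, 2, n_starts = 10, seed = 6)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_lt(abs(ours$log_likelihood - ref$loglik), 0.5)
  expect_gt(ari(lca_assignment(ours)$labels, ref$classification), 0.99)
})

test_that("relative entropy matches its defining formula", {
  mk <- function(post) structure(list(K = ncol(post), posteriors = post),
                                 class = "lca_model")
  expect_equal(relative_entropy(mk(rbind(c(1, 0), c(0, 1)))), 1.0)
  expect_equal(relative_entropy(mk(matrix(1 / 3, 4, 3))), 0.0)
  # hand case: rows (0.9, 0.1) and (0.5, 0.5), n = 2, K = 2
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1)) + log(2)
  expect_equal(relative_entropy(mk(rbind(c(0.9, 0.1), c(0.5, 0.5)))),
               1 - h / (2 * log(2)), tolerance = 1e-10)
  expect_equal(relative_entropy(mk(rbind(c(0.9, 0.1), c(0.5, 0.5)))),
               0.2655, tolerance = 1e-4)
  expect_error(relative_entropy(mk(matrix(1, 3, 1))), "K = 1")
})

test_that("replication bookkeeping drives the multi-start check", {
  set.seed(7)
  z <- rep(1:2, each = 200)
  X <- cbind(rnorm(400, ifelse(z == 1, -2.5, 2.5)), rnorm(400))
  m <- lca_fit(X, 2, n_starts = 30, seed = 8)
  expect_gte(m$n_start_replications, 20) # well-separated: almost all starts agree
  expect_true(replication_check(m))
  expect_true(replication_check(m, min_replications = 1)) # always passes
})

test_that("bootstrap LRT rejects for true two-class data and reports its formula", {
  set.seed(9)
  z <- rep(1:2, each = 250)
  X <- cbind(rnorm(500, ifelse(z == 1, -2, 2)), rnorm(500, ifelse(z == 1, 1, -1)))
  m1 <- lca_fit(X, 1, n_starts = 2, seed = 1)
  m2 <- lca_fit(X, 2, n_starts = 5, seed = 2)
  b <- bootstrap_lrt(X, m1, m2, B = 19, seed = 10, n_starts = 3)
  expect_lte(b$p_value, 0.05)
  expect_equal(b$p_value,
               (1 + sum(b$boot_stats >= b$observed)) / (b$B_effective + 1))
  expect_error(bootstrap_lrt(X, m2, m1, B = 9, seed = 1), "one more class")
  expect_error(bootstrap_lrt(X, m1, m2, B = 0, seed = 1), "B must be")
})

test_that("select_classes handles the trivial Kmax = 1 case", {
  set.seed(11)
  X <- matrix(rnorm(200), 100)
  sel <- select_classes(X, Kmax = 1, n_starts = 2, seed = 1)
  expect_equal(sel$selected_K, 1L)
  expect_true(is.na(sel$criteria$blrt_p[1]))
})

test_that("modal assignment is invariant to class-label permutation", {
  set.seed(12)
  z <- rep(1:2, each = 100)
  X <- matrix(rnorm(200, ifelse(z == 1, -3, 3)), ncol = 1)
  a1 <- lca_assignment(lca_fit(X, 2, n_starts = 5, seed = 1))
  a2 <- lca_assignment(lca_fit(X, 2, n_starts = 5, seed = 99))
  expect_equal(a1$labels, a2$labels) # size-ordering fixes the labels
})
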