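test_that("kmeans recovers well-separated blobs and matches the stats::kmeans objective", {
  b <- make_blobs(50, rbind(c(0, 0), c(10, 10)), sd = 1, seed = 2)
  km <- cluster_kmeans(b$X, 2, seed = 1)
  expect_equal(ari(km$labels, b$truth), 1.0)
  ref <- kmeans(b$X, 2, nstart = 10) # independent implementation
  expect_equal(km$objective_value, ref$tot.withinss, tolerance = 1e-8)
})

test_that("kmeans degenerate and contract cases hold", {
  X <- matrix(c(0, 0, 5, 5, 10, 10), ncol = 2, byrow = TRUE)
  km <- cluster_kmeans(X, 3, seed = 1)
  expect_equal(km$objective_value, 0)
  expect_equal(sort(unique(km$labels)), 1:3)
  expect_error(cluster_kmeans(rbind(X, X), 4, seed = 1), "distinct")
  # Lloyd inertia non-increasing on unstructured data
  set.seed(3)
  Xr <- matrix(rnorm(400), 100)
  km2 <- cluster_kmeans(Xr, 4, seed = 5, n_init = 3)
  expect_true(all(diff(km2$inertia_trace) <= 1e-9))
  # determinism
  expect_identical(cluster_kmeans(Xr, 3, seed = 9)$labels,
                   cluster_kmeans(Xr, 3, seed = 9)$labels)
})

test_that("pam matches exhaustive search on the 1-D example and cluster::pam elsewhere", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  pm <- cluster_pam(X, 2)
  expect_equal(pm$labels[1], pm$labels[2])
  expect_equal(pm$labels[3], pm$labels[4])
  expect_true(pm$labels[1] != pm$labels[3])
  # exhaustive oracle over all medoid pairs
  D <- as.matrix(dist(X))
  pairs <- combn(4, 2)
  costs <- apply(pairs, 2, function(m) sum(pmin(D[, m[1]], D[, m[2]])))
  expect_equal(pm$objective_value, min(costs))
  # the returned medoids achieve the exhaustive-search optimum
  expect_equal(sum(pmin(D[, pm$medoids[1]], D[, pm$medoids[2]])), min(costs))

  skip_if_not_installed("cluster")
  set.seed(8)
  Xr <- matrix(rnorm(200), 50)
  ours <- cluster_pam(Xr, 3)
  ref <- cluster::pam(Xr, 3)
  # same total dissimilarity (steepest-descent SWAP reaches the same optimum)
  expect_equal(ours$objective_value, unname(ref$objective["swap"]) * 50,
               tolerance = 1e-6)
  expect_equal(ari(ours$labels, ref$clustering), 1.0)
})

test_that("pam SWAP never increases cost and K=n gives cost 0", {
  set.seed(4)
  Xr <- matrix(rnorm(120), 40)
  pm <- cluster_pam(Xr, 4)
  expect_true(all(diff(pm$cost_trace) <= 1e-9))
  expect_lte(pm$objective_value, pm$cost_trace[1]) # final <= BUILD
  pm_all <- cluster_pam(matrix(rnorm(10), 10), 10)
  expect_equal(pm_all$objective_value, 0)
})

test_that("hierarchical clustering separates the 1-D example and nests", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  hc <- cluster_hierarchical(X, 2)
  expect_equal(hc$labels[1], hc$labels[2])
  expect_true(hc$labels[1] != hc$labels[3])
  expect_equal(cluster_hierarchical(X, 1)$K, 1L)
  # nesting: K-1 labels only merge two clusters of the K labels
  set.seed(5)
  Xr <- matrix(rnorm(300), 100)
  for (K in 3:5) {
    lk <- cluster_hierarchical(Xr, K)$labels
    lk1 <- cluster_hierarchical(Xr, K - 1)$labels
    # each K-cluster maps into exactly one (K-1)-cluster
    expect_true(all(tapply(lk1, lk, function(v) length(unique(v))) == 1))
  }
  expect_error(cluster_hierarchical(Xr, 2, linkage = "nope"))
})

test_that("spectral clustering separates concentric rings where kmeans cannot", {
  set.seed(6)
  n <- 100
  th <- runif(2 * n, 0, 2 * pi)
  r <- rep(c(2, 5), each = n) + rnorm(2 * n, sd = 0.1)
  X <- cbind(r * cos(th), r * sin(th))
  truth <- rep(1:2, each = n)
  sp <- cluster_spectral(X, 2, seed = 1, affinity = "knn", knn_k = 10)
  expect_equal(ari(sp$labels, truth), 1.0)
  km <- cluster_kmeans(X, 2, seed = 1)
  expect_lt(ari(km$labels, truth), 0.1)
  # normalised-Laplacian spectrum lies in [0, 2]
  expect_true(all(sp$laplacian_eigenvalues > -1e-8 &
                    sp$laplacian_eigenvalues < 2 + 1e-8))
})

test_that("spectral clustering agrees with kmeans on far-separated blobs", {
  b <- make_blobs(40, rbind(c(0, 0), c(20, 20)), seed = 7)
  sp <- cluster_spectral(b$X, 2, seed = 2)
  km <- cluster_kmeans(b$X, 2, seed = 2)
  expect_equal(ari(sp$labels, km$labels), 1.0)
  expect_error(cluster_spectral(matrix(1, 10, 3), 2, seed = 1), "degenerate")
})

test_that("cluster relabelling orders clusters by descending size", {
  a <- new_cluster_assignment(c(2L, 2L, 2L, 1L, 3L, 3L), 3L, "x")
  r <- relabel_by_size(a)
  expect_equal(tabulate(r$labels), c(3, 2, 1))
  expect_equal(r$raw_labels, c(2L, 2L, 2L, 1L, 3L, 3L))
})
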