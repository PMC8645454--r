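#' Cluster assignment container
#'
#' @param labels integer labels in 1..K, one per subject.
#' @param K number of clusters.
#' @param algorithm algorithm name.
#' @param seed seed used (NA for deterministic algorithms).
#' @param objective_value algorithm-specific objective (inertia, total
#'   dissimilarity, merge height; NA where not applicable).
#' @param ... extra diagnostic fields stored alongside.
#' @return object of class `cluster_assignment`.
#' @export
new_cluster_assignment <- function(labels, K, algorithm, seed = NA_integer_,
                                   objective_value = NA_real_, ...) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > K))
    stop("labels must lie in 1..K")
  if (length(unique(labels)) < K)
    stop("every cluster must be non-empty")
  structure(c(list(labels = labels, K = K, algorithm = algorithm,
                   seed = seed, objective_value = objective_value),
              list(...)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s, K=%d, n=%d, sizes: %s\n",
              x$algorithm, x$K, length(x$labels),
              paste(tabulate(x$labels, x$K), collapse = "/")))
  invisible(x)
}

#' Renumber clusters by descending size
#'
#' Reporting convention: cluster 1 is the largest. Ties broken by the
#' original label to keep the mapping deterministic.
#'
#' @param assignment a `cluster_assignment`.
#' @return the assignment with relabelled clusters (original labels kept
#'   in `$raw_labels`).
#' @export
relabel_by_size <- function(assignment) {
  sz <- tabulate(assignment$labels, assignment$K)
  ord <- order(-sz, seq_len(assignment$K))
  map <- integer(assignment$K)
  map[ord] <- seq_len(assignment$K)
  assignment$raw_labels <- assignment$labels
  assignment$labels <- map[assignment$labels]
  assignment
}

# k-means++ seeding
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- sqdist_to_centers(X, centers[1, , drop = FALSE])[, 1]
  for (k in seq_len(K - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[k, ] <- X[idx, ]
    d2 <- pmin(d2, sqdist_to_centers(X, centers[k, , drop = FALSE])[, 1])
  }
  centers
}

lloyd_once <- function(X, K, max_iter) {
  centers <- kmeanspp_init(X, K)
  n <- nrow(X)
  labels <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- sqdist_to_centers(X, centers)
    new_labels <- max.col(-D, ties.method = "first")
    # reseed empty clusters at the farthest point
    empty <- setdiff(seq_len(K), unique(new_labels))
    for (k in empty) {
      far <- which.max(D[cbind(seq_len(n), new_labels)])
      new_labels[far] <- k
      D[far, ] <- Inf
      D[far, k] <- 0
    }
    inertia <- sum(D[cbind(seq_len(n), new_labels)])
    trace <- c(trace, inertia)
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (k in seq_len(K))
      centers[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  list(labels = labels, centers = centers, inertia = trace[length(trace)],
       inertia_trace = trace)
}

#' K-means clustering (Lloyd iterations, k-means++ seeding)
#'
#' Runs Lloyd's algorithm from `n_init` k-means++ seedings and keeps the
#' restart with the lowest within-cluster sum of squares. The per-iteration
#' inertia trace of the winning restart is retained (`$inertia_trace`);
#' it is non-increasing by construction of the assignment/update steps.
#'
#' @param X complete, scaled numeric matrix (subjects x features).
#' @param K number of clusters (2 <= K <= n distinct rows).
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @return a `cluster_assignment` with `objective_value` = inertia.
#' @export
cluster_kmeans <- function(X, K, seed = 1L, n_init = 10L, max_iter = 300L) {
  X <- as.matrix(X)
  if (K > nrow(unique(X))) stop("K exceeds the number of distinct rows")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd_once(X, K, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  new_cluster_assignment(best$labels, K, "kmeans", seed = seed,
                         objective_value = best$inertia,
                         inertia_trace = best$inertia_trace,
                         centers = best$centers)
}

#' Partitioning around medoids (BUILD + SWAP)
#'
#' Classic PAM on Euclidean distances: greedy BUILD initialisation followed
#' by steepest-descent SWAP, accepting the best improving (medoid,
#' non-medoid) exchange until none improves. The total-dissimilarity trace
#' across accepted swaps (`$cost_trace`, starting at the BUILD cost) is
#' non-increasing by construction.
#'
#' @param X complete numeric matrix, or a `dist` object.
#' @param K number of medoids.
#' @param seed unused (PAM is deterministic); kept for interface parity.
#' @return a `cluster_assignment` with `objective_value` = total
#'   dissimilarity to assigned medoids, plus `$medoids` and `$cost_trace`.
#' @export
cluster_pam <- function(X, K, seed = NA_integer_) {
  D <- if (inherits(X, "dist")) as.matrix(X) else as.matrix(stats::dist(X))
  n <- nrow(D)
  if (K > n) stop("K exceeds n")
  # BUILD
  medoids <- which.min(colSums(D))
  d1 <- D[, medoids[1]]
  while (length(medoids) < K) {
    # gain of adding candidate c: sum over j of max(d1_j - D[j,c], 0)
    red <- colSums(pmax(d1 - D, 0))
    red[medoids] <- -Inf
    cand <- which.max(red)
    medoids <- c(medoids, cand)
    d1 <- pmin(d1, D[, cand])
  }
  cost <- function(meds) sum(apply(D[, meds, drop = FALSE], 1L, min))
  cur <- cost(medoids)
  trace <- cur
  repeat {
    Dm <- D[, medoids, drop = FALSE]
    n1 <- max.col(-Dm, ties.method = "first")      # index into medoids
    d1 <- Dm[cbind(seq_len(n), n1)]
    d2 <- apply(Dm, 1L, function(r) sort(r, partial = 2)[2])
    if (K == 1L) d2 <- rep(Inf, n)
    best_delta <- 0
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    if (!length(nonmed)) break
    for (mi in seq_along(medoids)) {
      # a_j: distance to nearest medoid after removing medoid mi
      a <- ifelse(n1 == mi, d2, d1)
      # new distance after adding candidate h: pmin(a, D[, h])
      newcost <- colSums(pmin(matrix(a, n, length(nonmed)),
                              D[, nonmed, drop = FALSE]))
      delta <- newcost - cur
      j <- which.min(delta)
      if (delta[j] < best_delta - 1e-12) {
        best_delta <- delta[j]
        best_swap <- c(mi, nonmed[j])
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cur <- cost(medoids)
    trace <- c(trace, cur)
  }
  Dm <- D[, medoids, drop = FALSE]
  labels <- max.col(-Dm, ties.method = "first")
  new_cluster_assignment(labels, K, "pam", seed = seed,
                         objective_value = cur, medoids = medoids,
                         cost_trace = trace)
}

#' Agglomerative hierarchical clustering
#'
#' Euclidean distances with Ward linkage by default (`stats::hclust`,
#' `ward.D2`); labels from cutting the merge tree at `K`.
#'
#' @param X complete numeric matrix or `dist`.
#' @param K number of clusters.
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @return a `cluster_assignment` with the `hclust` tree in `$tree` and
#'   `objective_value` = height of the merge that reduces K to K-1.
#' @export
cluster_hierarchical <- function(X, K, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  method <- c(ward = "ward.D2", complete = "complete", average = "average")[linkage]
  D <- if (inherits(X, "dist")) X else stats::dist(X)
  tree <- stats::hclust(D, method = method)
  labels <- stats::cutree(tree, k = K)
  n <- attr(D, "Size")
  height <- if (K < n) tree$height[n - K] else 0
  new_cluster_assignment(labels, K, "hierarchical",
                         objective_value = height, tree = tree,
                         linkage = linkage)
}

# symmetric normalised Laplacian spectral embedding (Ng-Jordan-Weiss)
spectral_embedding <- function(X, Kmax, affinity = "rbf", bandwidth = NULL,
                               knn_k = 10L) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  off <- D[upper.tri(D)]
  if (all(off == 0)) stop("degenerate affinity: all rows identical")
  if (affinity == "rbf") {
    sigma <- bandwidth %||% stats::median(off)
    A <- exp(-D^2 / (2 * sigma^2))
  } else {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(min(knn_k, n - 1L) + 1L)]
      A[i, nb] <- 1
    }
    A <- pmax(A, t(A)) # mutual-or symmetrisation
  }
  diag(A) <- 0
  deg <- rowSums(A)
  if (any(deg <= 0)) stop("degenerate affinity: isolated subject(s)")
  s <- 1 / sqrt(deg)
  M <- A * tcrossprod(s) # D^{-1/2} A D^{-1/2}
  eig <- eigen(M, symmetric = TRUE)
  list(vectors = eig$vectors, laplacian_eigenvalues = 1 - eig$values)
}

#' Spectral clustering (normalised-Laplacian embedding + k-means)
#'
#' Ng-Jordan-Weiss construction: RBF affinity on Euclidean distances
#' (bandwidth = median pairwise distance by default) or a symmetrised
#' k-nearest-neighbour graph; symmetric normalised Laplacian; the top-K
#' eigenvector rows are unit-normalised and clustered with k-means.
#'
#' @param X complete numeric matrix.
#' @param K number of clusters.
#' @param seed seed for the embedded k-means.
#' @param affinity `"rbf"` or `"knn"`.
#' @param bandwidth RBF bandwidth; default median pairwise distance.
#' @param knn_k neighbours for the k-NN graph.
#' @return a `cluster_assignment`; Laplacian eigenvalues (all in [0, 2])
#'   are kept in `$laplacian_eigenvalues`.
#' @export
cluster_spectral <- function(X, K, seed = 1L, affinity = c("rbf", "knn"),
                             bandwidth = NULL, knn_k = 10L) {
  affinity <- match.arg(affinity)
  emb <- spectral_embedding(as.matrix(X), K, affinity, bandwidth, knn_k)
  U <- emb$vectors[, seq_len(K), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- cluster_kmeans(U, K, seed = seed, n_init = 10L)
  new_cluster_assignment(km$labels, K, "spectral", seed = seed,
                         objective_value = km$objective_value,
                         laplacian_eigenvalues = emb$laplacian_eigenvalues,
                         affinity = affinity)
}
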