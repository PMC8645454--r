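run_algorithm <- function(X, algorithm, K, seed, algo_params = list()) {
  switch(algorithm,
    kmeans = do.call(cluster_kmeans,
                     c(list(X = X, K = K, seed = seed), algo_params)),
    pam = cluster_pam(X, K),
    hierarchical = do.call(cluster_hierarchical,
                           c(list(X = X, K = K), algo_params)),
    spectral = do.call(cluster_spectral,
                       c(list(X = X, K = K, seed = seed), algo_params)),
    stop("unknown algorithm: ", algorithm)
  )
}

# One pass over B resamples, accumulating co-clustering counts for every K
# in `Ks` on the SAME resamples. Expensive shared work (distance matrix,
# hclust tree, spectral embedding) is computed once per resample and
# reused across K.
consensus_matrices <- function(X, algorithm, Ks, B = 100L,
                               item_fraction = 0.8, feature_fraction = 1.0,
                               seed = 1L, algo_params = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(B >= 1L, item_fraction > 0, item_fraction <= 1,
            feature_fraction > 0, feature_fraction <= 1)
  n_sub <- max(2L, round(item_fraction * n))
  p_sub <- max(1L, round(feature_fraction * ncol(X)))
  conn <- lapply(Ks, function(k) matrix(0, n, n)) # co-cluster counts
  names(conn) <- as.character(Ks)
  samp <- matrix(0, n, n)                          # co-sampled counts
  n_failed <- 0L
  Kmax <- max(Ks)
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, b, stream = 11L)
    set.seed(sb)
    items <- sort(sample.int(n, n_sub))
    feats <- if (p_sub < ncol(X)) sort(sample.int(ncol(X), p_sub)) else seq_len(ncol(X))
    Xb <- X[items, feats, drop = FALSE]
    labs <- tryCatch({
      if (algorithm %in% c("pam", "hierarchical")) {
        D <- stats::dist(Xb)
        if (algorithm == "hierarchical") {
          linkage <- algo_params$linkage %||% "ward"
          method <- c(ward = "ward.D2", complete = "complete",
                      average = "average")[linkage]
          tree <- stats::hclust(D, method = method)
          lapply(Ks, function(k) stats::cutree(tree, k = k))
        } else {
          lapply(Ks, function(k) cluster_pam(D, k)$labels)
        }
      } else if (algorithm == "spectral") {
        emb <- spectral_embedding(Xb, Kmax,
                                  affinity = algo_params$affinity %||% "rbf",
                                  bandwidth = algo_params$bandwidth,
                                  knn_k = algo_params$knn_k %||% 10L)
        lapply(Ks, function(k) {
          U <- emb$vectors[, seq_len(k), drop = FALSE]
          rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
          cluster_kmeans(U / rn, k, seed = sb)$labels
        })
      } else {
        lapply(Ks, function(k) cluster_kmeans(Xb, k, seed = sb)$labels)
      }
    }, error = function(e) NULL)
    if (is.null(labs)) {
      n_failed <- n_failed + 1L
      next
    }
    samp[items, items] <- samp[items, items] + 1
    for (ki in seq_along(Ks)) {
      Z <- outer(labs[[ki]], labs[[ki]], "==")
      conn[[ki]][items, items] <- conn[[ki]][items, items] + Z
    }
  }
  if (n_failed == B) stop("all consensus resamples failed")
  mats <- lapply(conn, function(cm) {
    M <- cm / samp
    M[samp == 0] <- NA # never co-sampled: undefined, excluded from PAC
    M
  })
  list(matrices = mats, cosample_counts = samp, n_failed = n_failed,
       B = B, item_fraction = item_fraction, feature_fraction = feature_fraction,
       seed = seed)
}

#' Consensus matrix for one algorithm and cluster number
#'
#' Entry (i, j) is the fraction of resamples in which subjects i and j were
#' assigned to the same cluster, among resamples where both were sampled.
#' Pairs never co-sampled are `NA` and excluded from the PAC statistic.
#'
#' @param X complete, scaled feature matrix.
#' @param algorithm `"kmeans"`, `"pam"`, `"hierarchical"` or `"spectral"`.
#' @param K number of clusters per resample.
#' @param B number of resamples.
#' @param item_fraction fraction of subjects drawn per resample.
#' @param feature_fraction fraction of features drawn per resample.
#' @param seed master seed; each resample uses a derived child seed.
#' @param algo_params extra arguments for the algorithm.
#' @return symmetric n x n matrix with unit diagonal (where defined).
#' @export
consensus_matrix <- function(X, algorithm, K, B = 100L, item_fraction = 0.8,
                             feature_fraction = 1.0, seed = 1L,
                             algo_params = list()) {
  res <- consensus_matrices(X, algorithm, Ks = K, B = B,
                            item_fraction = item_fraction,
                            feature_fraction = feature_fraction,
                            seed = seed, algo_params = algo_params)
  res$matrices[[1]]
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of defined off-diagonal consensus entries strictly inside
#' `(lower, upper)` — equivalently CDF(upper-) - CDF(lower) of the
#' consensus-value distribution. Low PAC indicates a stable solution.
#'
#' @param consensus n x n consensus matrix (`NA` = undefined pair).
#' @param lower,upper ambiguity band, default (0.1, 0.9).
#' @return PAC in [0, 1].
#' @export
pac <- function(consensus, lower = 0.1, upper = 0.9) {
  stopifnot(lower >= 0, lower < upper, upper <= 1)
  v <- consensus[upper.tri(consensus)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no defined off-diagonal consensus entries")
  mean(v > lower & v < upper)
}

#' Select the number of clusters by consensus clustering and PAC
#'
#' Computes the consensus matrix and PAC for each K in `Kmin:Kmax` over a
#' shared set of resamples, selects the K minimising PAC (ties broken
#' toward smaller K), and refits the algorithm on the full data at the
#' selected K.
#'
#' @param X complete, scaled feature matrix.
#' @param algorithm algorithm name (see [consensus_matrix()]).
#' @param Kmin,Kmax cluster-number range (default 2..5).
#' @param B,item_fraction,feature_fraction,seed,algo_params resampling
#'   parameters, see [consensus_matrix()].
#' @param keep_matrices keep the per-K consensus matrices (memory).
#' @return object of class `consensus_result`: `pac_values` (named by K),
#'   `selected_K`, `assignment` (full-data refit, relabelled by size),
#'   `cdf_data` (long data.frame of consensus values per K) and the
#'   resampling settings.
#' @export
select_k <- function(X, algorithm, Kmin = 2L, Kmax = 5L, B = 100L,
                     item_fraction = 0.8, feature_fraction = 1.0, seed = 1L,
                     algo_params = list(), keep_matrices = FALSE) {
  stopifnot(Kmin >= 2L, Kmax >= Kmin)
  Ks <- seq.int(Kmin, Kmax)
  res <- consensus_matrices(X, algorithm, Ks, B = B,
                            item_fraction = item_fraction,
                            feature_fraction = feature_fraction,
                            seed = seed, algo_params = algo_params)
  pac_values <- vapply(res$matrices, pac, numeric(1))
  names(pac_values) <- as.character(Ks)
  selected_K <- Ks[which.min(pac_values)] # which.min takes the first = smallest K
  assignment <- relabel_by_size(
    run_algorithm(as.matrix(X), algorithm, selected_K,
                  seed = derive_seed(seed, 0L, stream = 13L),
                  algo_params = algo_params))
  cdf_data <- do.call(rbind, lapply(seq_along(Ks), function(i) {
    v <- res$matrices[[i]][upper.tri(res$matrices[[i]])]
    v <- v[!is.na(v)]
    data.frame(K = Ks[i], consensus = sort(v))
  }))
  structure(list(algorithm = algorithm, Ks = Ks, pac_values = pac_values,
                 selected_K = selected_K, assignment = assignment,
                 matrices = if (keep_matrices) res$matrices else NULL,
                 cdf_data = cdf_data, B = res$B, n_failed = res$n_failed,
                 item_fraction = item_fraction,
                 feature_fraction = feature_fraction, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s: selected K = %d\n  PAC: %s\n",
              x$algorithm, x$selected_K,
              paste(sprintf("K=%s %.4f", names(x$pac_values), x$pac_values),
                    collapse = ", ")))
  invisible(x)
}
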