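cluster_factor <- function(labels) {
  # factor with the largest cluster as reference level
  sz <- table(labels)
  ref <- names(sz)[order(-sz, as.integer(names(sz)))][1]
  stats::relevel(factor(labels), ref = ref)
}

#' Interaction likelihood-ratio test for heterogeneity of treatment effect
#'
#' Fits the full logistic model `y ~ cluster + w + cluster:w` (cluster as
#' K-1 dummies with the largest cluster as reference) against the reduced
#' model without the interaction; the statistic `2 (LL_full - LL_reduced)`
#' is referred to chi-squared with K-1 degrees of freedom. A significant
#' interaction (p < 0.05) is the HTE success criterion. Any empty
#' cluster-by-arm cell makes the interaction inestimable: the result is
#' returned flagged `estimable = FALSE` with the offending cell, never
#' silently continued.
#'
#' @param y binary outcome (death = 1).
#' @param w treatment arm (0/1).
#' @param cluster_labels integer cluster labels.
#' @return object of class `hte_test`: `lrt_statistic`, `df`, `p_value`,
#'   `significant`, `odds_ratios` (per-cluster table from
#'   [per_cluster_or()]), `mortality_by_cluster`, `chisq_p`, `estimable`.
#' @export
interaction_lrt <- function(y, w, cluster_labels) {
  K <- length(unique(cluster_labels))
  if (K < 2L) {
    return(structure(list(estimable = FALSE, reason = "single cluster",
                          K = K, lrt_statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, significant = FALSE,
                          odds_ratios = NULL,
                          mortality_by_cluster = tapply(y, cluster_labels, mean),
                          chisq_p = NA_real_),
                     class = "hte_test"))
  }
  tab <- table(cluster = cluster_labels, arm = w)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    return(structure(list(estimable = FALSE,
                          reason = sprintf("empty cell: cluster %s, arm %s",
                                           rownames(tab)[bad[1]],
                                           colnames(tab)[bad[2]]),
                          K = K, lrt_statistic = NA_real_,
                          df = as.integer(K - 1), p_value = NA_real_,
                          significant = FALSE, odds_ratios = NULL,
                          mortality_by_cluster = tapply(y, cluster_labels, mean),
                          chisq_p = NA_real_),
                     class = "hte_test"))
  }
  cl <- cluster_factor(cluster_labels)
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  full <- suppressWarnings(stats::glm(y ~ cl * w, family = stats::binomial(),
                                      control = ctrl))
  reduced <- suppressWarnings(stats::glm(y ~ cl + w, family = stats::binomial(),
                                         control = ctrl))
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  df <- K - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  chq <- mortality_chisq(y, cluster_labels)
  structure(list(estimable = TRUE, K = K, lrt_statistic = stat,
                 df = as.integer(df), p_value = p,
                 significant = p < 0.05,
                 odds_ratios = per_cluster_or(y, w, cluster_labels),
                 mortality_by_cluster = tapply(y, cluster_labels, mean),
                 chisq_statistic = chq$statistic, chisq_p = chq$p_value),
            class = "hte_test")
}

#' @export
print.hte_test <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<hte_test> not estimable (%s)\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf("<hte_test> LRT = %.3f on %d df, p = %.4g (%s); mortality chisq p = %.4g\n",
              x$lrt_statistic, x$df, x$p_value,
              if (x$significant) "significant HTE" else "no HTE", x$chisq_p))
  print(x$odds_ratios, digits = 3)
  invisible(x)
}

#' Per-cluster treatment odds ratios
#'
#' Within each cluster, the odds ratio of death under treatment from the
#' 2x2 treated/control x died/survived table, `(a d) / (b c)`, with a Wald
#' 95% CI on the log scale. With death coded 1 and treatment coded 1,
#' OR > 1 indicates harm and OR < 1 benefit. A 0.5 continuity correction
#' is applied to all four cells if (and only if) any cell is zero, and the
#' row is flagged. Clusters with an arm entirely absent are marked not
#' estimable.
#'
#' @param y binary outcome.
#' @param w treatment arm (0/1).
#' @param cluster_labels cluster labels.
#' @return data.frame: cluster, n, deaths, odds_ratio, ci_low, ci_high,
#'   corrected (logical), estimable (logical).
#' @export
per_cluster_or <- function(y, w, cluster_labels) {
  cls <- sort(unique(cluster_labels))
  out <- lapply(cls, function(cc) {
    sel <- cluster_labels == cc
    yt <- y[sel]; wt <- w[sel]
    if (length(unique(wt)) < 2L) {
      return(data.frame(cluster = cc, n = sum(sel), deaths = sum(yt),
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, corrected = FALSE,
                        estimable = FALSE))
    }
    a <- sum(yt == 1 & wt == 1) # died, treated
    b <- sum(yt == 0 & wt == 1) # survived, treated
    c_ <- sum(yt == 1 & wt == 0) # died, control
    d <- sum(yt == 0 & wt == 0) # survived, control
    corrected <- any(c(a, b, c_, d) == 0)
    if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    data.frame(cluster = cc, n = sum(sel), deaths = sum(yt),
               odds_ratio = or,
               ci_low = exp(log(or) - 1.96 * se),
               ci_high = exp(log(or) + 1.96 * se),
               corrected = corrected, estimable = TRUE)
  })
  do.call(rbind, out)
}

#' Chi-squared test of mortality differences across clusters
#'
#' Pearson chi-squared on the K x 2 cluster-by-death table without
#' continuity correction, df = K - 1. If any expected cell count is below
#' 1, the result carries `low_expected = TRUE` but is still returned.
#'
#' @param y binary outcome.
#' @param cluster_labels cluster labels (K >= 2).
#' @return list: `statistic`, `df`, `p_value`, `low_expected`.
#' @export
mortality_chisq <- function(y, cluster_labels) {
  K <- length(unique(cluster_labels))
  if (K < 2L) stop("mortality_chisq needs at least 2 clusters")
  tab <- table(cluster_labels, y)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, low_expected = any(expd < 1))
}

#' Gradient-boosting variable importance for cluster membership
#'
#' Trains an XGBoost classifier to predict the cluster labels from the
#' partitioning variables (never outcome or treatment) and returns each
#' feature's share of total split gain, normalised to sum to 1, with
#' ranks. Defaults: 200 trees, depth 3, learning rate 0.1; multiclass
#' softprob objective when K > 2.
#'
#' @param X feature matrix (unscaled features are fine; trees are
#'   scale-invariant).
#' @param cluster_labels labels from any clustering algorithm (K >= 2).
#' @param nrounds,max_depth,eta XGBoost hyperparameters.
#' @param seed integer seed.
#' @return data.frame of class `importance_table`: feature, gain_share,
#'   rank (sorted by rank; shares sum to 1).
#' @export
variable_importance <- function(X, cluster_labels, nrounds = 200L,
                                max_depth = 3L, eta = 0.1, seed = 1L) {
  X <- as.matrix(X)
  K <- length(unique(cluster_labels))
  if (K < 2L) stop("variable importance requires at least 2 clusters")
  lab0 <- as.integer(factor(cluster_labels)) - 1L
  params <- if (K == 2L) {
    list(objective = "binary:logistic", max_depth = max_depth, eta = eta,
         nthread = 1, seed = seed)
  } else {
    list(objective = "multi:softprob", num_class = K, max_depth = max_depth,
         eta = eta, nthread = 1, seed = seed)
  }
  set.seed(seed)
  dtr <- xgboost::xgb.DMatrix(X, label = lab0)
  fit <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                            verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  share <- stats::setNames(rep(0, ncol(X)), colnames(X))
  share[imp$Feature] <- imp$Gain
  share <- share / sum(share)
  out <- data.frame(feature = names(share), gain_share = unname(share))
  out <- out[order(-out$gain_share, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}
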