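#' Convert individual-treatment-effect estimates to sign clusters
#'
#' With death as the outcome and tau on the risk-difference scale (treated
#' minus control), positive tau means more deaths under treatment: the
#' "harm" cluster. Negative tau is the "benefit" cluster. Exact zeros are
#' resolved by `tie_rule` (default: benefit) and flagged.
#'
#' @param tau_hat numeric vector of per-subject effect estimates.
#' @param tie_rule `"benefit"` or `"harm"` for exact zeros.
#' @return a `cluster_assignment` with `$cluster_names`; if all subjects
#'   fall on one side, a single-cluster assignment flagged
#'   `$single_cluster = TRUE` (HTE not estimable downstream).
#' @export
ite_to_clusters <- function(tau_hat, tie_rule = c("benefit", "harm")) {
  tie_rule <- match.arg(tie_rule)
  if (any(!is.finite(tau_hat))) stop("tau_hat must be finite")
  harm <- if (tie_rule == "benefit") tau_hat > 0 else tau_hat >= 0
  n_ties <- sum(tau_hat == 0)
  if (all(harm) || all(!harm)) {
    a <- new_cluster_assignment(rep(1L, length(tau_hat)), 1L, "ite_sign")
    a$single_cluster <- TRUE
    a$cluster_names <- if (all(harm)) "harm" else "benefit"
    a$n_zero_ties <- n_ties
    return(a)
  }
  labels <- ifelse(harm, 2L, 1L)
  a <- new_cluster_assignment(labels, 2L, "ite_sign")
  a$cluster_names <- c("benefit", "harm")
  a$single_cluster <- FALSE
  a$n_zero_ties <- n_ties
  a
}

# pluggable base learners for the X-learner -------------------------------

fit_base_learner <- function(base_learner, X, y, seed) {
  if (is.function(base_learner)) return(base_learner(X, y, seed))
  switch(base_learner,
    rf = {
      fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = 300,
                            seed = seed, num.threads = 1L,
                            respect.unordered.factors = TRUE)
      function(Xnew) stats::predict(fit, data = as.data.frame(Xnew),
                                    num.threads = 1L)$predictions
    },
    gbm = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = 3,
                      eta = 0.1, nthread = 1, seed = seed),
        data = dtr, nrounds = 150, verbose = 0)
      function(Xnew) stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(Xnew)))
    },
    bart = stop("BART base learner adapter is not shipped; plug in a ",
                "function(X, y, seed) returning a predictor"),
    stop("unknown base learner: ", base_learner)
  )
}

#' X-learner treatment-effect estimates
#'
#' Two-stage meta-learner: stage 1 fits outcome surfaces mu0 on controls
#' and mu1 on treated; stage 2 forms imputed individual effects
#' `D1_i = y_i - mu0(x_i)` on the treated and `D0_i = mu1(x_i) - y_i` on
#' the controls, regresses them on covariates to get tau1 and tau0, and
#' blends `tau(x) = g(x) tau0(x) + (1 - g(x)) tau1(x)` with g the
#' propensity (constant 0.5 for a 1:1 RCT).
#'
#' @param X_train covariate matrix of the training subjects.
#' @param w treatment arm (0/1) of the training subjects.
#' @param y binary outcome of the training subjects.
#' @param X_test covariates to predict tau for.
#' @param base_learner `"rf"`, `"gbm"`, or a `function(X, y, seed)`
#'   returning a `function(Xnew) -> predictions`.
#' @param propensity constant treatment probability g in [0, 1].
#' @param seed integer seed.
#' @return numeric tau_hat for the rows of `X_test` (risk-difference
#'   scale, treated minus control).
#' @export
xlearner_tau <- function(X_train, w, y, X_test, base_learner = "rf",
                         propensity = 0.5, seed = 1L) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  if (!any(w == 1) || !any(w == 0)) stop("both arms required in training data")
  t_idx <- w == 1
  mu0 <- fit_base_learner(base_learner, X_train[!t_idx, , drop = FALSE],
                          y[!t_idx], derive_seed(seed, 1L))
  mu1 <- fit_base_learner(base_learner, X_train[t_idx, , drop = FALSE],
                          y[t_idx], derive_seed(seed, 2L))
  d1 <- y[t_idx] - mu0(X_train[t_idx, , drop = FALSE])
  d0 <- mu1(X_train[!t_idx, , drop = FALSE]) - y[!t_idx]
  tau1 <- fit_base_learner(base_learner, X_train[t_idx, , drop = FALSE],
                           d1, derive_seed(seed, 3L))
  tau0 <- fit_base_learner(base_learner, X_train[!t_idx, , drop = FALSE],
                           d0, derive_seed(seed, 4L))
  g <- propensity
  g * tau0(X_test) + (1 - g) * tau1(X_test)
}

# honest causal tree ------------------------------------------------------

grow_causal_tree <- function(X, w, y, split_idx, est_idx, min_leaf, max_depth,
                             mtry) {
  leaf_effect <- function(idx) {
    wt <- w[idx]
    if (!any(wt == 1) || !any(wt == 0)) return(NA_real_)
    mean(y[idx][wt == 1]) - mean(y[idx][wt == 0])
  }
  grow <- function(s_idx, e_idx, depth, parent_effect) {
    eff <- leaf_effect(e_idx)
    if (is.na(eff)) eff <- parent_effect # leaf missing an arm inherits
    node <- list(effect = eff)
    if (depth >= max_depth || length(s_idx) < 2 * min_leaf)
      return(node)
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- list(gain = 0)
    ws <- w[s_idx]; ys <- y[s_idx]
    for (j in feats) {
      xv <- X[s_idx, j]
      ord <- order(xv)
      xs <- xv[ord]; wo <- ws[ord]; yo <- ys[ord]
      n1 <- cumsum(wo); n0 <- cumsum(1 - wo)
      s1 <- cumsum(wo * yo); s0 <- cumsum((1 - wo) * yo)
      N1 <- n1[length(n1)]; N0 <- n0[length(n0)]
      S1 <- s1[length(s1)]; S0 <- s0[length(s0)]
      m <- length(xs)
      cuts <- which(xs[-m] < xs[-1]) # split between distinct values
      if (!length(cuts)) next
      valid <- n1[cuts] >= min_leaf & n0[cuts] >= min_leaf &
        (N1 - n1[cuts]) >= min_leaf & (N0 - n0[cuts]) >= min_leaf
      cuts <- cuts[valid]
      if (!length(cuts)) next
      tauL <- s1[cuts] / n1[cuts] - s0[cuts] / n0[cuts]
      tauR <- (S1 - s1[cuts]) / (N1 - n1[cuts]) - (S0 - s0[cuts]) / (N0 - n0[cuts])
      nL <- cuts; nR <- m - cuts
      gain <- nL * nR / m^2 * (tauL - tauR)^2
      gi <- which.max(gain)
      if (gain[gi] > best$gain) {
        best <- list(gain = gain[gi], feature = j,
                     threshold = (xs[cuts[gi]] + xs[cuts[gi] + 1]) / 2)
      }
    }
    if (best$gain <= 0) return(node)
    sl <- s_idx[X[s_idx, best$feature] <= best$threshold]
    sr <- s_idx[X[s_idx, best$feature] > best$threshold]
    el <- e_idx[X[e_idx, best$feature] <= best$threshold]
    er <- e_idx[X[e_idx, best$feature] > best$threshold]
    node$feature <- best$feature
    node$threshold <- best$threshold
    node$left <- grow(sl, el, depth + 1L, eff)
    node$right <- grow(sr, er, depth + 1L, eff)
    node
  }
  root_eff <- leaf_effect(est_idx)
  if (is.na(root_eff)) root_eff <- leaf_effect(c(split_idx, est_idx))
  grow(split_idx, est_idx, 0L, root_eff)
}

predict_causal_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (is.null(node$feature)) {
      out[idx] <<- node$effect
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    if (any(go_left)) rec(node$left, idx[go_left])
    if (any(!go_left)) rec(node$right, idx[!go_left])
  }
  if (n) rec(node, seq_len(n))
  out
}

#' Honest causal forest treatment-effect estimates
#'
#' An ensemble of honest causal trees: each tree is grown on a random
#' subsample split into a splitting half (chooses splits that maximise
#' between-child heterogeneity of the treatment-effect estimate) and an
#' estimation half (supplies the leaf effects, mean(y|w=1) - mean(y|w=0));
#' leaves missing an arm inherit their parent's estimate. Predictions
#' average over trees. When `X_test` is `NULL`, out-of-bag predictions on
#' the training subjects are returned: each subject is predicted only by
#' trees whose subsample excluded it.
#'
#' @param X_train covariates (training).
#' @param w,y treatment arm and binary outcome (training).
#' @param X_test covariates to predict; `NULL` for OOB training predictions.
#' @param n_trees number of trees.
#' @param honesty_fraction fraction of each subsample used for splitting.
#' @param min_leaf minimum subjects per arm per child (splitting half).
#' @param max_depth tree depth cap.
#' @param subsample_fraction subsample fraction per tree.
#' @param mtry features tried per split (default ceiling(sqrt(p))).
#' @param seed integer seed.
#' @return numeric tau_hat (risk-difference scale).
#' @export
causal_forest_tau <- function(X_train, w, y, X_test = NULL, n_trees = 100L,
                              honesty_fraction = 0.5, min_leaf = 10L,
                              max_depth = 4L, subsample_fraction = 0.5,
                              mtry = NULL, seed = 1L) {
  X_train <- as.matrix(X_train)
  if (!any(w == 1) || !any(w == 0)) stop("both arms required")
  if (min_leaf < 2L) stop("min_leaf must be >= 2 per arm")
  n <- nrow(X_train)
  mtry <- mtry %||% max(1L, ceiling(sqrt(ncol(X_train))))
  oob <- is.null(X_test)
  Xp <- if (oob) X_train else as.matrix(X_test)
  preds <- numeric(nrow(Xp))
  counts <- numeric(nrow(Xp))
  set.seed(seed)
  for (t in seq_len(n_trees)) {
    sub <- sample.int(n, max(4L, round(subsample_fraction * n)))
    nsp <- max(2L, round(honesty_fraction * length(sub)))
    split_idx <- sub[seq_len(nsp)]
    est_idx <- sub[-seq_len(nsp)]
    if (!any(w[est_idx] == 1) || !any(w[est_idx] == 0)) next
    tree <- grow_causal_tree(X_train, w, y, split_idx, est_idx,
                             min_leaf, max_depth, mtry)
    if (oob) {
      keep <- setdiff(seq_len(n), sub)
      if (!length(keep)) next
      preds[keep] <- preds[keep] +
        predict_causal_tree(tree, Xp[keep, , drop = FALSE])
      counts[keep] <- counts[keep] + 1
    } else {
      preds <- preds + predict_causal_tree(tree, Xp)
      counts <- counts + 1
    }
  }
  if (any(counts == 0))
    stop("some subjects received no tree predictions; increase n_trees")
  preds / counts
}

#' Cross-fitted individual treatment effects
#'
#' Partitions subjects into `n_folds` folds stratified by arm x outcome
#' and predicts each fold with an estimator trained on the remaining
#' folds, so every subject's tau_hat comes from models that never saw it.
#'
#' @param X covariate matrix (all subjects).
#' @param w,y treatment arm and binary outcome.
#' @param estimator `"xlearner"`, `"causal_forest"`, or a
#'   `function(X_train, w_train, y_train, X_test, seed)` returning tau.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @param ... passed to the estimator.
#' @return object of class `ite_result`: `tau_hat`, `fold_id`, `method`,
#'   and the derived sign-cluster `assignment`.
#' @export
crossfit_ite <- function(X, w, y, estimator = c("xlearner", "causal_forest"),
                         n_folds = 5L, seed = 1L, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  est_name <- if (is.function(estimator)) "custom" else match.arg(estimator)
  est_fun <- if (is.function(estimator)) estimator else switch(est_name,
    xlearner = function(Xtr, wtr, ytr, Xte, seed, ...)
      xlearner_tau(Xtr, wtr, ytr, Xte, seed = seed, ...),
    causal_forest = function(Xtr, wtr, ytr, Xte, seed, ...)
      causal_forest_tau(Xtr, wtr, ytr, Xte, seed = seed, ...)
  )
  set.seed(derive_seed(seed, 0L, stream = 29L))
  strata <- interaction(w, y, drop = TRUE)
  fold_id <- integer(n)
  for (s in levels(strata)) {
    idx <- sample(which(strata == s))
    fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  tau_hat <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    if (!any(w[tr] == 1) || !any(w[tr] == 0))
      stop("a training split is missing an arm; use fewer folds")
    tau_hat[!tr] <- est_fun(X[tr, , drop = FALSE], w[tr], y[tr],
                            X[!tr, , drop = FALSE],
                            seed = derive_seed(seed, f, stream = 31L), ...)
  }
  structure(list(tau_hat = tau_hat, fold_id = fold_id, method = est_name,
                 seed = seed, assignment = ite_to_clusters(tau_hat)),
            class = "ite_result")
}

#' @export
print.ite_result <- function(x, ...) {
  cat(sprintf("<ite_result> %s: mean tau=%.4f, %d benefit / %d harm\n",
              x$method, mean(x$tau_hat), sum(x$tau_hat <= 0), sum(x$tau_hat > 0)))
  invisible(x)
}

# model-based recursive partitioning --------------------------------------

mob_instability_p <- function(scores, v, n_perm, seed) {
  # max-|CUSUM| fluctuation statistic of the score contributions ordered
  # by v, calibrated by permuting v
  stat <- function(vv) {
    ord <- order(vv)
    s <- apply(scores[ord, , drop = FALSE], 2L, cumsum)
    sc <- apply(scores, 2L, function(col) stats::sd(col) * sqrt(length(col)))
    sc[sc == 0] <- 1
    max(abs(sweep(s, 2L, sc, "/")))
  }
  obs <- stat(v)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(v)))
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

mob_fit_node <- function(w, y) {
  fit <- suppressWarnings(stats::glm(y ~ w, family = stats::binomial()))
  p <- stats::fitted(fit)
  list(loglik = as.numeric(stats::logLik(fit)),
       coef = stats::coef(fit),
       scores = cbind((y - p), (y - p) * w))
}

#' Model-based recursive partitioning for treatment-effect modifiers
#'
#' Each node carries a logistic model `y ~ treatment`. Parameter
#' instability of the node model's score contributions against every
#' partitioning variable is assessed with a permutation max-CUSUM
#' fluctuation test (Bonferroni-adjusted across variables). If the
#' smallest adjusted p-value is below `alpha`, the node is split on that
#' variable at the cut maximising the sum of child log-likelihoods; the
#' recursion stops at `max_depth`, `min_node`, or when no instability
#' remains. Terminal nodes are the clusters.
#'
#' @param X partitioning-variable matrix.
#' @param w,y treatment arm and binary outcome.
#' @param alpha significance level for the instability test.
#' @param min_node minimum subjects per node.
#' @param max_depth depth cap (0 = never split).
#' @param n_perm permutations for the instability test.
#' @param n_cuts candidate split points per variable (quantile grid).
#' @param seed integer seed.
#' @return a `cluster_assignment` (algorithm `"mob"`); single-node trees
#'   yield a flagged single-cluster assignment. Node treatment
#'   coefficients are kept in `$node_models`.
#' @export
mob_partition <- function(X, w, y, alpha = 0.05, min_node = 50L,
                          max_depth = 3L, n_perm = 199L, n_cuts = 20L,
                          seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  labels <- rep(1L, n)
  node_models <- list()
  splits <- list()
  next_id <- 1L
  recurse <- function(idx, depth, node_seed) {
    id <- next_id; next_id <<- next_id + 1L
    labels[idx] <<- id
    fit <- mob_fit_node(w[idx], y[idx])
    node_models[[id]] <<- list(n = length(idx), coef = fit$coef)
    if (depth >= max_depth || length(idx) < 2 * min_node) return(invisible())
    if (length(unique(y[idx])) < 2L || length(unique(w[idx])) < 2L)
      return(invisible())
    pvals <- vapply(seq_len(ncol(X)), function(j) {
      v <- X[idx, j]
      if (length(unique(v)) < 2L) return(1)
      mob_instability_p(fit$scores, v, n_perm,
                        seed = derive_seed(node_seed, j, stream = 37L))
    }, numeric(1))
    pvals <- pmin(1, pvals * ncol(X)) # Bonferroni
    j <- which.min(pvals)
    if (pvals[j] >= alpha) return(invisible())
    v <- X[idx, j]
    cand <- unique(stats::quantile(v, probs = seq_len(n_cuts) / (n_cuts + 1),
                                   type = 1))
    best <- list(ll = -Inf, cut = NA)
    for (cu in cand) {
      li <- idx[v <= cu]; ri <- idx[v > cu]
      if (length(li) < min_node || length(ri) < min_node) next
      if (length(unique(w[li])) < 2L || length(unique(w[ri])) < 2L) next
      ll <- mob_fit_node(w[li], y[li])$loglik + mob_fit_node(w[ri], y[ri])$loglik
      if (ll > best$ll) best <- list(ll = ll, cut = cu)
    }
    if (!is.finite(best$ll)) return(invisible())
    splits[[length(splits) + 1L]] <<-
      list(feature = colnames(X)[j] %||% j, feature_index = j,
           cut = best$cut, depth = depth, n = length(idx))
    recurse(idx[v <= best$cut], depth + 1L, derive_seed(node_seed, 1L))
    recurse(idx[v > best$cut], depth + 1L, derive_seed(node_seed, 2L))
    invisible()
  }
  recurse(seq_len(n), 0L, seed)
  terminal <- sort(unique(labels))
  labels <- match(labels, terminal)
  K <- length(terminal)
  a <- new_cluster_assignment(labels, K, "mob", seed = seed)
  a$single_cluster <- K == 1L
  a$node_models <- node_models[terminal]
  a$splits <- splits
  relabel_by_size(a)
}
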