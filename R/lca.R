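lca_log_density <- function(X, types, params) {
  # n x K matrix of per-class log densities under conditional independence;
  # the Gaussian quadratic form is expanded so all classes are handled by
  # two matrix products instead of per-class sweeps
  n <- nrow(X)
  K <- length(params$weights)
  cont <- which(types == "continuous")
  bin <- which(types == "binary")
  ld <- matrix(0, n, K)
  if (length(cont)) {
    Xc <- X[, cont, drop = FALSE]
    inv_v <- 1 / params$variances            # K x p
    mu_iv <- params$means * inv_v
    quad <- Xc^2 %*% t(inv_v) - 2 * (Xc %*% t(mu_iv)) # n x K
    const <- rowSums(params$means^2 * inv_v) +
      rowSums(log(params$variances)) + length(cont) * log(2 * pi)
    ld <- ld - 0.5 * sweep(quad, 2L, const, "+")
  }
  if (length(bin)) {
    Xb <- X[, bin, drop = FALSE]
    lp <- log(params$probs)                   # K x p
    lq <- log(1 - params$probs)
    ld <- ld + Xb %*% t(lp - lq) +
      matrix(rowSums(lq), n, K, byrow = TRUE)
  }
  ld
}

lca_mstep <- function(X, types, R, var_floor, weight_floor) {
  n <- nrow(X)
  K <- ncol(R)
  nk <- colSums(R)
  weights <- pmax(nk / n, weight_floor)
  weights <- weights / sum(weights)
  cont <- which(types == "continuous")
  bin <- which(types == "binary")
  means <- variances <- probs <- NULL
  if (length(cont)) {
    Xc <- X[, cont, drop = FALSE]
    means <- crossprod(R, Xc) / nk
    ex2 <- crossprod(R, Xc^2) / nk
    variances <- pmax(ex2 - means^2, rep(var_floor, each = K))
  }
  if (length(bin)) {
    probs <- crossprod(R, X[, bin, drop = FALSE]) / nk
    probs <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
  }
  list(weights = weights, means = means, variances = variances, probs = probs,
       raw_nk = nk)
}

lca_em_once <- function(X, types, K, init_labels, tol, max_iter,
                        var_floor, weight_floor) {
  n <- nrow(X)
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), init_labels)] <- 1
  params <- lca_mstep(X, types, R, var_floor, weight_floor)
  ll_trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- sweep(lca_log_density(X, types, params), 2L, log(params$weights), "+")
    lse <- row_logsumexp(ld)
    new_ll <- sum(lse)
    R <- exp(ld - lse)
    ll_trace <- c(ll_trace, new_ll)
    if (is.finite(ll) && abs(new_ll - ll) < tol * (abs(ll) + 1)) {
      ll <- new_ll
      break
    }
    ll <- new_ll
    params <- lca_mstep(X, types, R, var_floor, weight_floor)
  }
  degenerate <- any(params$raw_nk / n < weight_floor)
  list(params = params, posteriors = R, log_likelihood = ll,
       ll_trace = ll_trace, degenerate = degenerate)
}

#' Fit a latent class/profile mixture model by EM with multi-start
#'
#' Finite mixture under within-class conditional independence: Gaussian
#' indicators with class-specific means and variances, Bernoulli indicators
#' for binary features. EM is restarted from `n_starts` random hard
#' assignments; the best-log-likelihood solution is returned together with
#' the number of starts that reproduced the best log-likelihood within
#' `replication_tol` (the multi-start replication count used by
#' [replication_check()]). The observed log-likelihood is non-decreasing
#' across EM iterations; the trace of the winning start is kept in
#' `$ll_trace`. A variance floor (`var_floor_frac` times each feature's
#' marginal variance) and a class-weight floor of `1/(10 n)` guard against
#' degenerate solutions; starts that still collapse a class are discarded
#' and an error is raised only if every start degenerates.
#'
#' @param X complete numeric matrix (subjects x indicators).
#' @param K number of latent classes (K >= 1).
#' @param types character vector per column: `"continuous"` or `"binary"`.
#' @param n_starts number of random starts.
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @param replication_tol absolute log-likelihood tolerance within which a
#'   start counts as reproducing the best solution.
#' @param var_floor_frac variance floor as a fraction of marginal variance.
#' @return object of class `lca_model`.
#' @export
lca_fit <- function(X, K, types = rep("continuous", ncol(X)),
                    n_starts = 20L, seed = 1L, tol = 1e-8, max_iter = 500L,
                    replication_tol = 0.01, var_floor_frac = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of subjects")
  stopifnot(length(types) == ncol(X), all(types %in% c("continuous", "binary")))
  if (anyNA(X)) stop("X must be complete (impute first)")
  cont <- which(types == "continuous")
  var_floor <- if (length(cont))
    pmax(var_floor_frac * apply(X[, cont, drop = FALSE], 2L, stats::var), 1e-10)
  else numeric(0)
  weight_floor <- 1 / (10 * n)
  set.seed(seed)
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    init <- sample.int(K, n, replace = TRUE)
    # guarantee every class is seeded
    init[sample.int(n, K)] <- seq_len(K)
    fits[[s]] <- lca_em_once(X, types, K, init, tol, max_iter,
                             var_floor, weight_floor)
  }
  ok <- !vapply(fits, `[[`, logical(1), "degenerate")
  if (!any(ok)) stop("all EM starts degenerated (class weight below floor)")
  lls <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  lls[!ok] <- -Inf
  best <- which.max(lls)
  n_repl <- sum(ok & abs(lls - lls[best]) <= replication_tol)
  fit <- fits[[best]]
  p_cont <- length(cont)
  p_bin <- sum(types == "binary")
  d <- (K - 1) + K * (2 * p_cont + p_bin)
  post <- fit$posteriors
  rel_ent <- if (K >= 2) {
    pe <- post * log(ifelse(post > 0, post, 1))
    min(max(1 - sum(-pe) / (n * log(K)), 0), 1)
  } else NA_real_
  structure(list(
    K = K, types = types, weights = fit$params$weights,
    means = fit$params$means, variances = fit$params$variances,
    probs = fit$params$probs,
    log_likelihood = fit$log_likelihood,
    bic = -2 * fit$log_likelihood + d * log(n),
    n_params = d,
    relative_entropy = rel_ent,
    smallest_class_fraction = min(colMeans(post)),
    posteriors = post, ll_trace = fit$ll_trace,
    n_start_replications = n_repl, n_starts = n_starts,
    n = n, seed = seed
  ), class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("<lca_model> K=%d, LL=%.2f, BIC=%.2f, entropy=%s, smallest class=%.1f%%, %d/%d starts replicated\n",
              x$K, x$log_likelihood, x$bic,
              if (is.na(x$relative_entropy)) "NA" else sprintf("%.3f", x$relative_entropy),
              100 * x$smallest_class_fraction,
              x$n_start_replications, x$n_starts))
  invisible(x)
}

#' Did the best log-likelihood replicate across enough starts?
#'
#' Models whose maximum likelihood was not reproduced in at least
#' `min_replications` random starts are treated as unstable and excluded
#' from class-number selection.
#'
#' @param model an `lca_model`.
#' @param min_replications required replication count (default 20).
#' @return logical.
#' @export
replication_check <- function(model, min_replications = 20L) {
  model$n_start_replications >= min_replications
}

#' Relative entropy of an LCA solution
#'
#' `1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`, clamped to [0, 1]:
#' 1 means perfectly crisp posterior class assignment, 0 means uniform
#' posteriors.
#'
#' @param model an `lca_model` with K >= 2.
#' @return relative entropy in [0, 1].
#' @export
relative_entropy <- function(model) {
  if (model$K < 2L) stop("relative entropy is undefined for K = 1")
  post <- model$posteriors
  pe <- post * log(ifelse(post > 0, post, 1))
  min(max(1 - sum(-pe) / (nrow(post) * log(model$K)), 0), 1)
}

lca_simulate <- function(model, n, seed) {
  set.seed(seed)
  cls <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  types <- model$types
  X <- matrix(0, n, length(types))
  cont <- which(types == "continuous")
  bin <- which(types == "binary")
  if (length(cont)) {
    for (j in seq_along(cont)) {
      X[, cont[j]] <- stats::rnorm(n, model$means[cls, j],
                                   sqrt(model$variances[cls, j]))
    }
  }
  if (length(bin)) {
    for (j in seq_along(bin)) {
      X[, bin[j]] <- stats::rbinom(n, 1L, model$probs[cls, j])
    }
  }
  X
}

#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' The reference distribution of `2 (LL_K - LL_{K-1})` is simulated by
#' generating `B` datasets from the fitted (K-1)-class model and refitting
#' both models on each; `p = (1 + #{bootstrap stat >= observed}) / (B + 1)`.
#' This bootstrap LRT serves as the primary class-enumeration criterion in
#' place of the VLMR test, whose non-standard null distribution is not
#' re-derived here.
#'
#' @param X the observed (complete) indicator matrix.
#' @param model_small fitted `lca_model` with K-1 classes.
#' @param model_large fitted `lca_model` with K classes.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param n_starts EM starts per bootstrap refit (fewer than the primary
#'   fit; the refits only need the LR statistic).
#' @param tol,max_iter EM settings for the bootstrap refits; looser than
#'   the primary fit since only the LR statistic is needed.
#' @return list with `p_value`, `observed`, `boot_stats`, `B_effective`.
#' @export
bootstrap_lrt <- function(X, model_small, model_large, B = 49L, seed = 1L,
                          n_starts = 5L, tol = 1e-6, max_iter = 100L) {
  if (B < 1L) stop("B must be >= 1")
  if (model_large$K != model_small$K + 1L)
    stop("model_large must have exactly one more class than model_small")
  obs <- 2 * (model_large$log_likelihood - model_small$log_likelihood)
  n <- nrow(as.matrix(X))
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, b, stream = 17L)
    Xb <- lca_simulate(model_small, n, seed = sb)
    res <- tryCatch({
      f0 <- lca_fit(Xb, model_small$K, types = model_small$types,
                    n_starts = n_starts, seed = derive_seed(sb, 1L),
                    tol = tol, max_iter = max_iter)
      f1 <- lca_fit(Xb, model_large$K, types = model_small$types,
                    n_starts = n_starts, seed = derive_seed(sb, 2L),
                    tol = tol, max_iter = max_iter)
      2 * (f1$log_likelihood - f0$log_likelihood)
    }, error = function(e) NA_real_)
    stats_b[b] <- res
  }
  ok <- !is.na(stats_b)
  if (!any(ok)) stop("all bootstrap refits failed")
  list(p_value = (1 + sum(stats_b[ok] >= obs)) / (sum(ok) + 1),
       observed = obs, boot_stats = stats_b[ok], B_effective = sum(ok))
}

#' Enumerate latent classes: fit K = 1..Kmax and select
#'
#' Fits models for K = 1..Kmax. The primary selection rule is sequential:
#' starting from K = 2, the (K vs K-1) bootstrap LRT must reject at
#' `alpha`, the model must pass [replication_check()], and its smallest
#' class must hold at least `smallest_class_floor` of subjects; the
#' largest K satisfying the chain of criteria is selected (selection stops
#' at the first failing K). BIC, relative entropy, smallest-class fraction
#' and the LRT p-values for every K are reported in `$criteria`.
#'
#' @param X complete indicator matrix.
#' @param Kmax largest number of classes considered.
#' @param types per-column indicator types.
#' @param n_starts EM starts for the primary fits.
#' @param B bootstrap LRT replicates.
#' @param alpha LRT significance level.
#' @param min_replications multi-start replication requirement.
#' @param smallest_class_floor minimum smallest-class fraction.
#' @param seed integer seed.
#' @param boot_starts EM starts inside each bootstrap refit.
#' @return object of class `lca_selection`: `selected_K`, `model` (the
#'   selected `lca_model`), `models` (all fits), `criteria` (data.frame).
#' @export
select_classes <- function(X, Kmax = 5L, types = rep("continuous", ncol(X)),
                           n_starts = 20L, B = 49L, alpha = 0.05,
                           min_replications = 20L, smallest_class_floor = 0.05,
                           seed = 1L, boot_starts = 5L) {
  X <- as.matrix(X)
  models <- lapply(seq_len(Kmax), function(k)
    lca_fit(X, k, types = types, n_starts = n_starts,
            seed = derive_seed(seed, k, stream = 19L)))
  p_values <- rep(NA_real_, Kmax)
  selected <- 1L
  if (Kmax >= 2L) {
    for (k in 2:Kmax) {
      blrt <- bootstrap_lrt(X, models[[k - 1]], models[[k]], B = B,
                            seed = derive_seed(seed, k, stream = 23L),
                            n_starts = boot_starts)
      p_values[k] <- blrt$p_value
      eligible <- blrt$p_value < alpha &&
        replication_check(models[[k]], min_replications) &&
        models[[k]]$smallest_class_fraction >= smallest_class_floor
      if (eligible) selected <- k else break
    }
  }
  criteria <- data.frame(
    K = seq_len(Kmax),
    log_likelihood = vapply(models, `[[`, numeric(1), "log_likelihood"),
    n_replications = vapply(models, `[[`, numeric(1), "n_start_replications"),
    bic = vapply(models, `[[`, numeric(1), "bic"),
    entropy = vapply(models, `[[`, numeric(1), "relative_entropy"),
    smallest_class = vapply(models, `[[`, numeric(1), "smallest_class_fraction"),
    blrt_p = p_values
  )
  structure(list(selected_K = selected, model = models[[selected]],
                 models = models, criteria = criteria, alpha = alpha,
                 min_replications = min_replications,
                 smallest_class_floor = smallest_class_floor, seed = seed),
            class = "lca_selection")
}

#' @export
print.lca_selection <- function(x, ...) {
  cat(sprintf("<lca_selection> selected K = %d\n", x$selected_K))
  print(x$criteria, digits = 4)
  invisible(x)
}

#' Modal class assignment from a fitted LCA model
#'
#' Assigns each subject to its highest-posterior class and renumbers the
#' classes by descending size.
#'
#' @param model an `lca_model`.
#' @return a `cluster_assignment` (algorithm `"lca"`).
#' @export
lca_assignment <- function(model) {
  labels <- max.col(model$posteriors, ties.method = "first")
  # guard: a class can be empty in modal assignment even if weights > 0
  used <- sort(unique(labels))
  if (length(used) < model$K) {
    labels <- match(labels, used)
    K <- length(used)
  } else K <- model$K
  relabel_by_size(new_cluster_assignment(labels, K, "lca", seed = model$seed,
                                         objective_value = NA_real_))
}
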