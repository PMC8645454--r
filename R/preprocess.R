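#' Log-transform skewed continuous features
#'
#' Continuous features are natural-log transformed when either (a) their
#' metadata flags them as log-normal, or (b) their sample skewness exceeds
#' `skew_threshold` in absolute value (the operational rule for
#' "non-normally distributed"). The metadata flag always wins over the
#' skewness rule so repeated runs are deterministic.
#'
#' Non-positive values under a flagged transform are an error unless
#' `offset_policy = "half_min_positive"`, in which case half the smallest
#' positive value of the feature is added to the whole feature before
#' taking logs.
#'
#' @param cohort an `rct_cohort`.
#' @param skew_threshold absolute sample-skewness cutoff (default 1.0).
#' @param offset_policy `"error"` or `"half_min_positive"`.
#' @return list with elements `cohort` (transformed) and `log_flags`
#'   (named logical: which features were transformed) and `offsets`
#'   (named numeric: offset added per transformed feature, 0 if none).
#' @export
log_transform <- function(cohort, skew_threshold = 1.0,
                          offset_policy = c("error", "half_min_positive")) {
  offset_policy <- match.arg(offset_policy)
  meta <- cohort$metadata
  cont <- meta$name[meta$type == "continuous"]
  flags <- stats::setNames(logical(length(cont)), cont)
  offsets <- stats::setNames(numeric(length(cont)), cont)
  for (f in cont) {
    v <- cohort$data[[f]]
    flagged <- meta$lognormal[meta$name == f]
    if (!flagged && abs(sample_skewness(v)) > skew_threshold) flagged <- TRUE
    if (!flagged) next
    nonpos <- !is.na(v) & v <= 0
    off <- 0
    if (any(nonpos)) {
      if (offset_policy == "error") {
        bad <- which(nonpos)[1]
        stop(sprintf("feature '%s' has non-positive value %.4g at row %d; set offset_policy",
                     f, v[bad], bad))
      }
      pos <- v[!is.na(v) & v > 0]
      if (!length(pos)) stop(sprintf("feature '%s' has no positive values", f))
      off <- 0.5 * min(pos)
    }
    cohort$data[[f]] <- log(v + off)
    flags[f] <- TRUE
    offsets[f] <- off
  }
  list(cohort = cohort, log_flags = flags, offsets = offsets)
}

#' Single imputation with chained equations
#'
#' Fills missing feature cells with one completed dataset by iterative
#' per-feature conditional imputation: predictive mean matching (donor
#' pool of `pmm_k`) for continuous features, a logistic-regression
#' Bernoulli draw for binary features. Cells are initialised by random
#' draws from the observed marginals, then features are revisited in order
#' of increasing missingness for `n_iterations` cycles. The fixed
#' iteration count is the convergence rule; the same seed always yields
#' the same completed data, and the single completed dataset is intended
#' to be shared by every downstream algorithm in a run.
#'
#' @param cohort an `rct_cohort` (treatment/outcome complete).
#' @param n_iterations number of chained-equation cycles (default 10).
#' @param seed integer seed.
#' @param pmm_k donor-pool size for predictive mean matching (default 5).
#' @return list with `cohort` (completed), `imputed_mask` (logical matrix,
#'   subjects x features, TRUE where a cell was imputed) and `visit_order`.
#' @export
impute_chained <- function(cohort, n_iterations = 10L, seed = 1L, pmm_k = 5L) {
  meta <- cohort$metadata
  feats <- meta$name
  X <- as.data.frame(cohort$data[, feats, drop = FALSE])
  mask <- is.na(as.matrix(X))
  colnames(mask) <- feats
  if (!any(mask)) {
    return(list(cohort = cohort, imputed_mask = mask, visit_order = character(0)))
  }
  all_missing <- feats[colSums(!mask) == 0]
  if (length(all_missing))
    stop("feature(s) with 100% missingness cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  set.seed(seed)
  n <- nrow(X)
  # marginal initialisation
  for (f in feats) {
    m <- mask[, f]
    if (any(m)) X[[f]][m] <- sample(X[[f]][!m], sum(m), replace = TRUE)
  }
  visit <- feats[order(colSums(mask))]
  visit <- visit[colSums(mask)[visit] > 0]
  types <- stats::setNames(meta$type, meta$name)
  for (it in seq_len(n_iterations)) {
    for (f in visit) {
      m <- mask[, f]
      others <- setdiff(feats, f)
      Z <- stats::model.matrix(~ ., data = X[, others, drop = FALSE])
      y <- X[[f]]
      if (types[f] == "continuous") {
        fit <- stats::lm.fit(Z[!m, , drop = FALSE], y[!m])
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        yhat_obs <- drop(Z[!m, , drop = FALSE] %*% beta)
        yhat_mis <- drop(Z[m, , drop = FALSE] %*% beta)
        obs_vals <- y[!m]
        imp <- vapply(yhat_mis, function(p) {
          d <- abs(yhat_obs - p)
          donors <- order(d)[seq_len(min(pmm_k, length(d)))]
          obs_vals[sample(donors, 1L)]
        }, numeric(1))
        X[[f]][m] <- imp
      } else {
        yo <- y[!m]
        if (length(unique(yo)) < 2L) {
          X[[f]][m] <- yo[1]
        } else {
          fit <- suppressWarnings(
            stats::glm.fit(Z[!m, , drop = FALSE], yo,
                           family = stats::binomial()))
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          pr <- stats::plogis(drop(Z[m, , drop = FALSE] %*% beta))
          X[[f]][m] <- stats::rbinom(sum(m), 1L, pr)
        }
      }
    }
  }
  cohort$data[, feats] <- X
  list(cohort = cohort, imputed_mask = mask, visit_order = visit)
}

#' Z-scale continuous features to mean 0, SD 1
#'
#' Binary (and dummy-coded categorical) features pass through unchanged:
#' scaling 0/1 indicators would distort Euclidean geometry relative to the
#' standardised continuous features. SD uses the n-1 convention.
#'
#' @param cohort complete `rct_cohort` (run imputation first).
#' @return list with `cohort` (scaled) and `centers`/`scales` (named
#'   numeric vectors over the continuous features).
#' @export
zscale <- function(cohort) {
  meta <- cohort$metadata
  cont <- meta$name[meta$type == "continuous"]
  if (anyNA(cohort$data[, meta$name, drop = FALSE]))
    stop("zscale requires complete data; impute first")
  centers <- scales <- stats::setNames(numeric(length(cont)), cont)
  for (f in cont) {
    v <- cohort$data[[f]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance feature cannot be z-scaled: ", f)
    centers[f] <- mean(v)
    scales[f] <- s
    cohort$data[[f]] <- (v - centers[f]) / s
  }
  list(cohort = cohort, centers = centers, scales = scales)
}

#' Preprocess a cohort: log-transform, impute, z-scale
#'
#' Applies the fixed pipeline order log -> impute -> scale exactly once and
#' returns both the processed cohort and a replayable `preprocess_state`
#' recording every decision (log flags and offsets, imputation seed and
#' visit order, imputed-cell mask, scaling centers and scales).
#'
#' @param cohort an `rct_cohort`.
#' @param skew_threshold,offset_policy passed to [log_transform()].
#' @param n_iterations,pmm_k passed to [impute_chained()].
#' @param seed imputation seed.
#' @param scale if `FALSE`, skip z-scaling (the supervised estimators use
#'   unscaled features).
#' @return list with `cohort` (processed, complete), `unscaled_cohort`
#'   (post-imputation, pre-scaling) and `state` (class `preprocess_state`).
#' @export
preprocess <- function(cohort, skew_threshold = 1.0,
                       offset_policy = "half_min_positive",
                       n_iterations = 10L, pmm_k = 5L, seed = 1L,
                       scale = TRUE) {
  lt <- log_transform(cohort, skew_threshold, offset_policy)
  im <- impute_chained(lt$cohort, n_iterations = n_iterations, seed = seed,
                       pmm_k = pmm_k)
  unscaled <- im$cohort
  centers <- scales <- NULL
  out <- unscaled
  if (scale) {
    zs <- zscale(unscaled)
    out <- zs$cohort
    centers <- zs$centers
    scales <- zs$scales
  }
  state <- structure(list(
    skew_threshold = skew_threshold, offset_policy = offset_policy,
    log_flags = lt$log_flags, offsets = lt$offsets,
    n_iterations = n_iterations, pmm_k = pmm_k, seed = seed,
    visit_order = im$visit_order, imputed_mask = im$imputed_mask,
    centers = centers, scales = scales, scaled = scale
  ), class = "preprocess_state")
  list(cohort = out, unscaled_cohort = unscaled, state = state)
}

#' Replay a stored preprocessing state on the same input cohort
#'
#' Re-applies the recorded log flags/offsets, re-runs the chained
#' imputation with the recorded seed and settings, and scales with the
#' recorded centers and scales, reproducing the original output exactly.
#'
#' @param state a `preprocess_state`.
#' @param cohort the same raw input cohort.
#' @return the processed cohort.
#' @export
replay_preprocess <- function(state, cohort) {
  for (f in names(state$log_flags)[state$log_flags]) {
    cohort$data[[f]] <- log(cohort$data[[f]] + state$offsets[f])
  }
  im <- impute_chained(cohort, n_iterations = state$n_iterations,
                       seed = state$seed, pmm_k = state$pmm_k)
  cohort <- im$cohort
  if (isTRUE(state$scaled)) {
    for (f in names(state$centers)) {
      cohort$data[[f]] <- (cohort$data[[f]] - state$centers[f]) / state$scales[f]
    }
  }
  cohort
}
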