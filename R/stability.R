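#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table of the two labelings with pair counts C(., 2):
#' `(Index - Expected) / (MaxIndex - Expected)`. 1 means identical
#' partitions, 0 chance-level agreement. When both partitions are trivial
#' (each a single cluster, or each all singletons) the denominator is 0 and
#' the ARI is defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors (any label values).
#' @return ARI in [-1, 1].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index - expected == 0) return(1.0)
  (sum_ij - expected) / (max_index - expected)
}

#' Re-run one algorithm across random seeds and summarise stability
#'
#' Executes `n_runs` full pipeline replicates on the same raw cohort, each
#' re-seeding BOTH the single imputation and the clustering/ITE stage from
#' a child seed derived from `master_seed` (run i depends only on
#' (master_seed, i), so adding runs never changes earlier ones). Each
#' run's clusters are tested for HTE; pairwise adjusted Rand indices
#' across runs quantify cluster stability. The number of clusters `K` is
#' fixed across runs (pass the K selected by a primary run); LCA runs rely
#' on their internal multi-start protocol instead of a single seed.
#'
#' @param cohort raw `rct_cohort` (missingness intact).
#' @param algorithm one of `"lca"`, `"kmeans"`, `"pam"`, `"hierarchical"`,
#'   `"spectral"`, `"mob"`, `"causal_forest"`, `"xlearner"`.
#' @param K number of clusters for the unsupervised algorithms (ignored by
#'   the supervised ones and MOB).
#' @param n_runs number of replicate runs (default 10).
#' @param master_seed master seed.
#' @param include_biomarkers drop biomarker features if `FALSE`.
#' @param algo_params extra parameters for the algorithm.
#' @param preprocess_params extra parameters for [preprocess()].
#' @return object of class `stability_report`: per-run assignments and
#'   `hte` results, `ari_matrix`, `mean_ari` (off-diagonal mean),
#'   `n_significant_runs`, `run_seeds`, `failed_runs`.
#' @export
run_replicates <- function(cohort, algorithm, K = 2L, n_runs = 10L,
                           master_seed = 1L, include_biomarkers = TRUE,
                           algo_params = list(), preprocess_params = list()) {
  stopifnot(n_runs >= 2L)
  runs <- vector("list", n_runs)
  seeds <- vapply(seq_len(n_runs), function(i) derive_seed(master_seed, i),
                  integer(1))
  for (i in seq_len(n_runs)) {
    runs[[i]] <- tryCatch({
      pre <- do.call(preprocess, c(list(cohort = cohort, seed = seeds[i]),
                                   preprocess_params))
      a <- fit_assignment(pre, algorithm, K = K, seed = seeds[i],
                          include_biomarkers = include_biomarkers,
                          algo_params = algo_params)
      hte <- interaction_lrt(pre$cohort$data$death90,
                             pre$cohort$data$treatment, a$labels)
      list(assignment = a, hte = hte, error = NULL)
    }, error = function(e) list(assignment = NULL, hte = NULL,
                                error = conditionMessage(e)))
  }
  ok <- which(vapply(runs, function(r) is.null(r$error), logical(1)))
  ari_matrix <- matrix(NA_real_, n_runs, n_runs)
  diag(ari_matrix) <- 1
  for (i in ok) for (j in ok) if (i < j) {
    ari_matrix[i, j] <- ari_matrix[j, i] <-
      ari(runs[[i]]$assignment$labels, runs[[j]]$assignment$labels)
  }
  offdiag <- ari_matrix[upper.tri(ari_matrix)]
  n_sig <- sum(vapply(runs[ok], function(r)
    isTRUE(r$hte$significant), logical(1)))
  structure(list(algorithm = algorithm, K = K, n_runs = n_runs,
                 run_seeds = seeds, runs = runs,
                 ari_matrix = ari_matrix,
                 mean_ari = mean(offdiag, na.rm = TRUE),
                 n_significant_runs = n_sig,
                 failed_runs = setdiff(seq_len(n_runs), ok)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s, K=%d, %d runs: mean ARI = %.3f, HTE significant in %d/%d runs%s\n",
              x$algorithm, x$K, x$n_runs, x$mean_ari, x$n_significant_runs,
              x$n_runs - length(x$failed_runs),
              if (length(x$failed_runs))
                sprintf(" (%d failed)", length(x$failed_runs)) else ""))
  invisible(x)
}

#' Long-format summary of a stability report
#' @param report a `stability_report`.
#' @return data.frame: run, algorithm, K, p_value, significant, failed.
#' @export
stability_long <- function(report) {
  do.call(rbind, lapply(seq_len(report$n_runs), function(i) {
    r <- report$runs[[i]]
    data.frame(run = i, algorithm = report$algorithm, K = report$K,
               p_value = if (is.null(r$hte)) NA_real_ else r$hte$p_value,
               significant = isTRUE(r$hte$significant),
               failed = !is.null(r$error))
  }))
}

#' Paired benchmark with and without protein biomarkers
#'
#' Executes [run_benchmark()] twice on identical settings and seeds, once
#' with all partitioning variables and once with every biomarker-flagged
#' feature excluded, to measure how much HTE detection depends on the
#' biomarkers.
#'
#' @param config a [run_config()].
#' @return list: `with_biomarkers`, `without_biomarkers` (benchmark
#'   bundles), `excluded_features` (the biomarker-flagged set).
#' @export
biomarker_exclusion_run <- function(config) {
  cohort <- resolve_cohort(config)
  excluded <- cohort$metadata$name[cohort$metadata$is_biomarker]
  if (!length(excluded))
    stop("no biomarker-flagged features in the cohort metadata")
  cfg_with <- config
  cfg_with$include_biomarkers <- TRUE
  cfg_without <- config
  cfg_without$include_biomarkers <- FALSE
  if (!is.null(config$out_dir)) {
    cfg_with$out_dir <- file.path(config$out_dir, "with_biomarkers")
    cfg_without$out_dir <- file.path(config$out_dir, "without_biomarkers")
  }
  list(with_biomarkers = run_benchmark(cfg_with),
       without_biomarkers = run_benchmark(cfg_without),
       excluded_features = excluded)
}
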