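ALGORITHMS <- c("lca", "kmeans", "pam", "hierarchical", "spectral",
                "mob", "causal_forest", "xlearner")

#' Benchmark run configuration
#'
#' @param input either a [generator_config()] (a synthetic cohort is
#'   generated and missingness applied) or a
#'   `list(csv = , metadata = )` pointing at files for [read_cohort()].
#' @param algorithms subset of `lca`, `kmeans`, `pam`, `hierarchical`,
#'   `spectral`, `mob`, `causal_forest`, `xlearner`.
#' @param k_range cluster-number range for consensus selection (default
#'   2..5) and LCA enumeration (1..max).
#' @param consensus list of consensus parameters (`B`, `item_fraction`,
#'   `feature_fraction`).
#' @param lca list of LCA parameters (`n_starts`, `B`, `boot_starts`,
#'   `min_replications`, `smallest_class_floor`).
#' @param ite list of ITE parameters (`n_folds`, plus estimator arguments
#'   such as `n_trees`).
#' @param include_biomarkers use biomarker features (default TRUE).
#' @param stability run the seed-perturbation analysis per algorithm.
#' @param n_runs replicate runs for the stability analysis.
#' @param master_seed one seed governing the entire run; every stage uses
#'   a derived child seed.
#' @param out_dir optional output directory for the report bundle.
#' @return a validated `run_config`.
#' @export
run_config <- function(input = generator_config(),
                       algorithms = c("lca", "kmeans"),
                       k_range = 2:5,
                       consensus = list(B = 100L, item_fraction = 0.8,
                                        feature_fraction = 1.0),
                       lca = list(n_starts = 30L, B = 49L, boot_starts = 4L,
                                  min_replications = 20L,
                                  smallest_class_floor = 0.05),
                       ite = list(n_folds = 5L),
                       include_biomarkers = TRUE,
                       stability = FALSE, n_runs = 10L,
                       master_seed = 1L, out_dir = NULL) {
  bad <- setdiff(algorithms, ALGORITHMS)
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  if (min(k_range) < 2L) stop("k_range must start at 2 or above")
  structure(list(input = input, algorithms = algorithms, k_range = k_range,
                 consensus = consensus, lca = lca, ite = ite,
                 include_biomarkers = include_biomarkers,
                 stability = stability, n_runs = n_runs,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "run_config")
}

resolve_cohort <- function(config) {
  input <- config$input
  if (inherits(input, "generator_config")) {
    apply_missingness(generate_cohort(input), input)
  } else if (is.list(input) && !is.null(input$csv)) {
    read_cohort(input$csv, input$metadata)
  } else stop("config$input must be a generator_config or list(csv=, metadata=)")
}

# fit one algorithm on a preprocessed cohort at a FIXED K (selection is
# done separately); shared by run_benchmark and run_replicates
fit_assignment <- function(pre, algorithm, K, seed, include_biomarkers = TRUE,
                           algo_params = list()) {
  Xs <- feature_matrix(pre$cohort, include_biomarkers)
  w <- pre$cohort$data$treatment
  y <- pre$cohort$data$death90
  switch(algorithm,
    lca = {
      types <- feature_types(pre$cohort, include_biomarkers)
      m <- do.call(lca_fit, c(list(X = Xs, K = K, types = unname(types),
                                   seed = seed),
                              algo_params))
      a <- lca_assignment(m)
      a$model <- m
      a
    },
    mob = {
      Xu <- feature_matrix(pre$unscaled_cohort, include_biomarkers)
      do.call(mob_partition, c(list(X = Xu, w = w, y = y, seed = seed),
                               algo_params))
    },
    xlearner = ,
    causal_forest = {
      Xu <- feature_matrix(pre$unscaled_cohort, include_biomarkers)
      res <- do.call(crossfit_ite,
                     c(list(X = Xu, w = w, y = y, estimator = algorithm,
                            seed = seed), algo_params))
      a <- res$assignment
      a$algorithm <- algorithm
      a$ite <- res
      a
    },
    relabel_by_size(run_algorithm(Xs, algorithm, K, seed = seed,
                                  algo_params = algo_params))
  )
}

#' Run the full clustering-for-HTE benchmark
#'
#' Executes the analysis plan end to end: preprocess once (log-transform,
#' single chained-equation imputation, z-scaling), then for every
#' configured algorithm select the number of clusters (consensus/PAC for
#' the distance-based methods, bootstrap-LRT enumeration for LCA, sign of
#' the cross-fitted ITE for the supervised methods), assign subjects,
#' test the clusters for HTE with the interaction likelihood-ratio test,
#' compute per-cluster odds ratios and the cluster-mortality chi-squared
#' test, and attribute variable importance with gradient boosting. A
#' failing algorithm is recorded with its error; the others continue.
#'
#' @param config a [run_config()].
#' @return a `benchmark_bundle`: `cohort` (raw), `preprocess_state`,
#'   `results` (per algorithm: `assignment`, `selection`, `hte`,
#'   `importance`, `error`), `report` (tidy data.frame, one row per
#'   cluster), and `config`. If `config$out_dir` is set the bundle is also
#'   written as CSV/JSON files.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  ms <- config$master_seed
  cohort <- resolve_cohort(config)
  pre <- preprocess(cohort, seed = derive_seed(ms, 0L, stream = 1L))
  inc <- config$include_biomarkers
  Xs <- feature_matrix(pre$cohort, inc)
  Xu <- feature_matrix(pre$unscaled_cohort, inc)
  w <- pre$cohort$data$treatment
  y <- pre$cohort$data$death90
  kmin <- min(config$k_range)
  kmax <- max(config$k_range)
  results <- list()
  for (ai in seq_along(config$algorithms)) {
    alg <- config$algorithms[ai]
    seed_a <- derive_seed(ms, ai, stream = 2L)
    results[[alg]] <- tryCatch({
      sel <- NULL
      if (alg %in% c("kmeans", "pam", "hierarchical", "spectral")) {
        sel <- select_k(Xs, alg, Kmin = kmin, Kmax = kmax,
                        B = config$consensus$B %||% 100L,
                        item_fraction = config$consensus$item_fraction %||% 0.8,
                        feature_fraction = config$consensus$feature_fraction %||% 1.0,
                        seed = seed_a)
        assignment <- sel$assignment
      } else if (alg == "lca") {
        types <- feature_types(pre$cohort, inc)
        sel <- select_classes(Xs, Kmax = kmax, types = unname(types),
                              n_starts = config$lca$n_starts %||% 30L,
                              B = config$lca$B %||% 49L,
                              boot_starts = config$lca$boot_starts %||% 4L,
                              min_replications = config$lca$min_replications %||% 20L,
                              smallest_class_floor = config$lca$smallest_class_floor %||% 0.05,
                              seed = seed_a)
        assignment <- lca_assignment(sel$model)
      } else {
        ap <- if (alg == "mob") list() else config$ite %||% list()
        assignment <- fit_assignment(pre, alg, K = 2L, seed = seed_a,
                                     include_biomarkers = inc,
                                     algo_params = ap)
      }
      hte <- interaction_lrt(y, w, assignment$labels)
      importance <- if (assignment$K >= 2L)
        variable_importance(Xu, assignment$labels,
                            seed = derive_seed(ms, ai, stream = 3L))
      else NULL
      list(assignment = assignment, selection = sel, hte = hte,
           importance = importance, error = NULL)
    }, error = function(e) list(assignment = NULL, selection = NULL,
                                hte = NULL, importance = NULL,
                                error = conditionMessage(e)))
  }
  stability <- NULL
  if (isTRUE(config$stability)) {
    stability <- lapply(stats::setNames(config$algorithms, config$algorithms),
                        function(alg) {
      K <- results[[alg]]$assignment$K %||% 2L
      run_replicates(cohort, alg, K = K, n_runs = config$n_runs,
                     master_seed = derive_seed(ms, match(alg, ALGORITHMS),
                                               stream = 5L),
                     include_biomarkers = inc)
    })
  }
  report <- benchmark_report(results)
  bundle <- structure(list(cohort = cohort, preprocess_state = pre$state,
                           results = results, stability = stability,
                           report = report, config = config,
                           elapsed_seconds = proc.time()[["elapsed"]] - t0),
                      class = "benchmark_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

benchmark_report <- function(results) {
  rows <- lapply(names(results), function(alg) {
    r <- results[[alg]]
    if (!is.null(r$error)) {
      return(data.frame(algorithm = alg, K = NA_integer_, cluster = NA_integer_,
                        n = NA_integer_, mortality = NA_real_,
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, lrt_p = NA_real_,
                        chisq_p = NA_real_, significant = NA,
                        error = r$error))
    }
    a <- r$assignment
    h <- r$hte
    if (is.null(h$odds_ratios)) {
      return(data.frame(algorithm = alg, K = a$K, cluster = 1L,
                        n = length(a$labels),
                        mortality = unname(h$mortality_by_cluster[1]),
                        odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, lrt_p = NA_real_,
                        chisq_p = NA_real_, significant = FALSE,
                        error = h$reason %||% NA_character_))
    }
    or <- h$odds_ratios
    data.frame(algorithm = alg, K = a$K, cluster = or$cluster, n = or$n,
               mortality = as.numeric(h$mortality_by_cluster[as.character(or$cluster)]),
               odds_ratio = or$odds_ratio, ci_low = or$ci_low,
               ci_high = or$ci_high, lrt_p = h$p_value, chisq_p = h$chisq_p,
               significant = h$significant, error = NA_character_)
  })
  do.call(rbind, rows)
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("<benchmark_bundle> %d subjects, %d algorithm(s), %.1f s\n",
              n_subjects(x$cohort), length(x$results), x$elapsed_seconds))
  agg <- unique(x$report[, c("algorithm", "K", "lrt_p", "significant")])
  print(agg, row.names = FALSE, digits = 4)
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("assignments", "hte", "importance", "stability"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  cfg <- bundle$config
  cfg_json <- list(algorithms = cfg$algorithms, k_range = cfg$k_range,
                   consensus = cfg$consensus, lca = cfg$lca, ite = cfg$ite,
                   include_biomarkers = cfg$include_biomarkers,
                   master_seed = cfg$master_seed,
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  st <- bundle$preprocess_state
  jsonlite::write_json(
    list(log_flags = as.list(st$log_flags), offsets = as.list(st$offsets),
         n_iterations = st$n_iterations, pmm_k = st$pmm_k, seed = st$seed,
         visit_order = st$visit_order,
         n_imputed_cells = sum(st$imputed_mask),
         centers = as.list(st$centers), scales = as.list(st$scales)),
    file.path(out_dir, "preprocess_state.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (alg in names(bundle$results)) {
    r <- bundle$results[[alg]]
    if (is.null(r$assignment)) next
    utils::write.csv(
      data.frame(subject_id = bundle$cohort$data$subject_id,
                 cluster = r$assignment$labels),
      file.path(out_dir, "assignments", paste0(alg, ".csv")),
      row.names = FALSE)
    if (!is.null(r$importance))
      utils::write.csv(r$importance,
                       file.path(out_dir, "importance", paste0(alg, ".csv")),
                       row.names = FALSE)
    h <- r$hte
    jsonlite::write_json(
      list(estimable = h$estimable, K = h$K, lrt_statistic = h$lrt_statistic,
           df = h$df, p_value = h$p_value, significant = h$significant,
           chisq_p = h$chisq_p,
           mortality_by_cluster = as.list(h$mortality_by_cluster),
           odds_ratios = h$odds_ratios),
      file.path(out_dir, "hte", paste0(alg, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$stability)) {
    for (alg in names(bundle$stability)) {
      utils::write.csv(stability_long(bundle$stability[[alg]]),
                       file.path(out_dir, "stability", paste0(alg, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(bundle$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
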