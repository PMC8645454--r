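#' Subject-level RCT cohort
#'
#' An `rct_cohort` bundles the subject-level table of a randomised trial
#' (binary treatment arm, binary 90-day mortality, baseline partitioning
#' variables with missing values coded `NA`) with per-feature metadata
#' declaring each variable's type, whether it is a research protein
#' biomarker, and whether it lives on a log-normal scale.
#'
#' @param data data.frame with columns `subject_id`, `treatment` (0/1),
#'   `death90` (0/1) and one column per feature.
#' @param metadata data.frame with columns `name`, `type`
#'   (`"continuous"`, `"binary"` or `"categorical"`), `is_biomarker`
#'   (logical) and `lognormal` (logical).
#' @param true_class optional integer vector of latent class labels; only
#'   present for synthetic cohorts.
#' @return an object of class `rct_cohort`.
#' @export
new_cohort <- function(data, metadata, true_class = NULL) {
  stopifnot(is.data.frame(data), is.data.frame(metadata))
  req <- c("subject_id", "treatment", "death90")
  if (!all(req %in% names(data)))
    stop("cohort data must contain columns: ", paste(req, collapse = ", "))
  if (anyNA(data$treatment) || anyNA(data$death90))
    stop("treatment and death90 must be non-missing for all subjects")
  if (!all(data$treatment %in% c(0, 1)))
    stop("treatment must be binary 0/1; offending row(s): ",
         paste(utils::head(which(!data$treatment %in% c(0, 1)), 5), collapse = ", "))
  if (!all(data$death90 %in% c(0, 1)))
    stop("death90 must be binary 0/1; offending row(s): ",
         paste(utils::head(which(!data$death90 %in% c(0, 1)), 5), collapse = ", "))
  if (anyDuplicated(data$subject_id))
    stop("duplicate subject_id values")
  need <- c("name", "type", "is_biomarker", "lognormal")
  if (!all(need %in% names(metadata)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  missing_feats <- setdiff(metadata$name, names(data))
  if (length(missing_feats))
    stop("features declared in metadata but absent from data: ",
         paste(missing_feats, collapse = ", "))
  if (!all(metadata$type %in% c("continuous", "binary", "categorical")))
    stop("unknown feature type in metadata")
  if (!is.null(true_class)) {
    stopifnot(length(true_class) == nrow(data))
    true_class <- as.integer(true_class)
  }
  structure(list(data = data, metadata = metadata, true_class = true_class),
            class = "rct_cohort")
}

#' @export
print.rct_cohort <- function(x, ...) {
  n <- nrow(x$data)
  p <- nrow(x$metadata)
  nb <- sum(x$metadata$is_biomarker)
  miss <- sum(is.na(x$data[, x$metadata$name, drop = FALSE]))
  cat(sprintf("<rct_cohort> %d subjects, %d features (%d biomarkers), %d missing cells%s\n",
              n, p, nb, miss,
              if (!is.null(x$true_class)) ", synthetic (true_class present)" else ""))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort an `rct_cohort`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$data)

#' Extract the partitioning-variable matrix of a cohort
#'
#' Returns only the baseline features: clustering code that consumes this
#' matrix can never see the outcome or the treatment arm, which enforces
#' the outcome/treatment-agnostic contract of the unsupervised algorithms.
#' Categorical features are expanded to 0/1 dummies (one column per
#' non-reference level).
#'
#' @param cohort an `rct_cohort`.
#' @param include_biomarkers if `FALSE`, biomarker-flagged features are
#'   dropped (the biomarker-exclusion sensitivity analysis).
#' @return numeric matrix, one row per subject; `NA` marks missing cells.
#' @export
feature_matrix <- function(cohort, include_biomarkers = TRUE) {
  meta <- cohort$metadata
  if (!include_biomarkers) meta <- meta[!meta$is_biomarker, , drop = FALSE]
  if (nrow(meta) == 0L) stop("no features left after filtering")
  cols <- list()
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    v <- cohort$data[[nm]]
    if (meta$type[i] == "categorical") {
      lev <- sort(unique(stats::na.omit(as.character(v))))
      for (l in lev[-1]) {
        cols[[paste0(nm, "_", l)]] <- as.numeric(as.character(v) == l)
      }
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' Feature types aligned with the columns of [feature_matrix()]
#'
#' @param cohort an `rct_cohort`.
#' @param include_biomarkers drop biomarker-flagged features if `FALSE`.
#' @return named character vector (`"continuous"`/`"binary"`), one entry
#'   per column of the corresponding [feature_matrix()].
#' @export
feature_types <- function(cohort, include_biomarkers = TRUE) {
  meta <- cohort$metadata
  if (!include_biomarkers) meta <- meta[!meta$is_biomarker, , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(meta))) {
    if (meta$type[i] == "categorical") {
      v <- cohort$data[[meta$name[i]]]
      lev <- sort(unique(stats::na.omit(as.character(v))))
      out <- c(out, stats::setNames(rep("binary", length(lev) - 1L),
                                    paste0(meta$name[i], "_", lev[-1])))
    } else {
      out <- c(out, stats::setNames(meta$type[i], meta$name[i]))
    }
  }
  out
}

#' Write a cohort to CSV plus a JSON metadata sidecar
#'
#' @param cohort an `rct_cohort`.
#' @param csv_path path for the subject-level CSV (missing cells written
#'   as empty fields).
#' @param metadata_path path for the JSON sidecar declaring column roles.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, csv_path, metadata_path) {
  df <- cohort$data
  if (!is.null(cohort$true_class)) df$true_class <- cohort$true_class
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  meta <- list(
    id_col = "subject_id", treatment_col = "treatment", outcome_col = "death90",
    has_true_class = !is.null(cohort$true_class),
    features = cohort$metadata
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, metadata_path))
}

#' Read a cohort from CSV plus its JSON metadata sidecar
#'
#' Empty and `NA` cells become missing feature values; treatment and
#' outcome must be complete and binary. Per-feature missingness is
#' recorded in the returned object's `missing_summary` attribute.
#'
#' @param csv_path subject-level CSV.
#' @param metadata_path JSON sidecar written by [write_cohort()] (or
#'   hand-authored with the same fields).
#' @return an `rct_cohort`.
#' @export
read_cohort <- function(csv_path, metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  fmeta <- as.data.frame(meta$features, stringsAsFactors = FALSE)
  ren <- c(subject_id = meta$id_col %||% "subject_id",
           treatment = meta$treatment_col %||% "treatment",
           death90 = meta$outcome_col %||% "death90")
  for (std in names(ren)) {
    src <- ren[[std]]
    if (!src %in% names(df)) stop("input CSV lacks declared column: ", src)
    names(df)[names(df) == src] <- std
  }
  unknown <- setdiff(names(df), c("subject_id", "treatment", "death90",
                                  "true_class", fmeta$name))
  if (length(unknown))
    stop("columns in CSV not declared in metadata: ",
         paste(unknown, collapse = ", "))
  tc <- if (isTRUE(meta$has_true_class) && "true_class" %in% names(df))
    df$true_class else NULL
  df$true_class <- NULL
  cohort <- new_cohort(df, fmeta, true_class = tc)
  fm <- cohort$data[, fmeta$name, drop = FALSE]
  attr(cohort, "missing_summary") <-
    data.frame(feature = fmeta$name, n_missing = colSums(is.na(fm)),
               frac_missing = colMeans(is.na(fm)), row.names = NULL)
  cohort
}
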