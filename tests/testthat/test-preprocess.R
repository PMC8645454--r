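test_that("log transform follows the metadata flag and the skewness rule", {
  co <- make_tiny_cohort(n = 200)
  set.seed(1)
  co$data$il6 <- exp(rnorm(200, 2, 1))  # log-normal, flagged anyway
  co$data$age <- rnorm(200, 50, 5)      # symmetric, must not be transformed
  lt <- log_transform(co)
  expect_true(lt$log_flags["il6"])
  expect_false(lt$log_flags["age"])
  expect_equal(lt$cohort$data$il6, log(co$data$il6))
  expect_equal(lt$cohort$data$age, co$data$age)

  # skewness rule triggers without a metadata flag
  co2 <- co
  co2$metadata$lognormal <- FALSE
  co2$data$il6 <- exp(rnorm(200, 2, 1.2))
  expect_gt(abs(hteclust:::sample_skewness(co2$data$il6)), 1)
  expect_true(log_transform(co2)$log_flags["il6"])
})

test_that("all-ones feature maps to zeros; offsets handle non-positive values", {
  co <- make_tiny_cohort(n = 6)
  co$data$il6 <- rep(1, 6)
  lt <- log_transform(co)
  expect_equal(lt$cohort$data$il6, rep(0, 6))

  co$data$il6 <- c(0, 2, 4, 8, 3, 5)
  expect_error(log_transform(co, offset_policy = "error"), "il6.*row 1")
  lt2 <- log_transform(co, offset_policy = "half_min_positive")
  expect_equal(lt2$offsets[["il6"]], 0.5 * 2)
  expect_equal(lt2$cohort$data$il6[1], log(0 + 0.5 * 2))
})

test_that("zscale centres and scales with the n-1 convention", {
  co <- make_tiny_cohort(n = 3)
  co$data$il6 <- c(1, 2, 3)
  co$data$age <- c(10, 20, 60)
  zs <- zscale(co)
  expect_equal(zs$cohort$data$il6, c(-1, 0, 1))
  expect_equal(zs$cohort$data$sex_male, co$data$sex_male) # binary untouched
  # idempotence
  zs2 <- zscale(zs$cohort)
  expect_equal(zs2$cohort$data$il6, zs$cohort$data$il6, tolerance = 1e-10)
  co$data$age <- rep(5, 3)
  expect_error(zscale(co), "age")
})

test_that("chained imputation fills only masked cells, deterministically", {
  cfg <- generator_config(n_subjects = 300, missing_rate = 0.1, seed = 4)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  im1 <- impute_chained(co, seed = 9)
  im2 <- impute_chained(co, seed = 9)
  expect_identical(im1$cohort$data, im2$cohort$data)
  expect_false(anyNA(im1$cohort$data[, co$metadata$name]))
  for (f in co$metadata$name) {
    obs <- !is.na(co$data[[f]])
    expect_identical(im1$cohort$data[[f]][obs], co$data[[f]][obs])
  }
  # complete data passes through untouched
  co_full <- generate_cohort(generator_config(n_subjects = 50, seed = 4))
  expect_identical(impute_chained(co_full, seed = 1)$cohort, co_full)
  # fully missing feature is an error
  co_bad <- co
  co_bad$data$il6 <- NA_real_
  expect_error(impute_chained(co_bad, seed = 1), "il6")
})

test_that("PMM imputation beats marginal-mean imputation on a correlated feature", {
  set.seed(77)
  n <- 2000
  x_complete <- rnorm(n)
  y_true <- 0.8 * x_complete + sqrt(1 - 0.8^2) * rnorm(n) # corr 0.8
  mask <- runif(n) < 0.2
  dat <- data.frame(subject_id = as.character(seq_len(n)),
                    treatment = rep_len(0:1, n), death90 = rep_len(c(0L, 1L), n),
                    x = x_complete, y = ifelse(mask, NA, y_true))
  meta <- data.frame(name = c("x", "y"), type = "continuous",
                     is_biomarker = FALSE, lognormal = FALSE)
  co <- new_cohort(dat, meta)
  im <- impute_chained(co, seed = 5)
  rmse_pmm <- sqrt(mean((im$cohort$data$y[mask] - y_true[mask])^2))
  rmse_mean <- sqrt(mean((mean(y_true[!mask]) - y_true[mask])^2))
  expect_lt(rmse_pmm, rmse_mean)
})

test_that("a stored preprocess state replays bit-wise on the same input", {
  cfg <- generator_config(n_subjects = 200, missing_rate = 0.1, seed = 6)
  co <- apply_missingness(generate_cohort(cfg), cfg)
  pre <- preprocess(co, seed = 13)
  replayed <- replay_preprocess(pre$state, co)
  expect_identical(pre$cohort$data, replayed$data)
  expect_false(anyNA(pre$cohort$data[, co$metadata$name]))
  # imputed-cell bookkeeping matches the observed missingness
  expect_identical(unname(colSums(pre$state$imputed_mask)),
                   unname(colSums(is.na(as.matrix(co$data[, co$metadata$name])))))
})
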