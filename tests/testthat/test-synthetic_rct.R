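test_that("invalid generator configurations are rejected before sampling", {
  expect_error(generator_config(class_prevalence = c(0.5, 0.4)), "sum to 1")
  expect_error(generator_config(mortality_base_logit = -1), "per class")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  fs <- default_feature_spec()
  fs$class_location[[1]] <- 1 # wrong length
  expect_error(generator_config(feature_spec = fs), "offending")
})

test_that("same seed and config give a byte-identical cohort", {
  cfg <- generator_config(n_subjects = 200, seed = 7)
  a <- apply_missingness(generate_cohort(cfg), cfg)
  b <- apply_missingness(generate_cohort(cfg), cfg)
  expect_identical(a, b)
})

test_that("treatment is randomised independently of the latent class", {
  cfg <- generator_config(n_subjects = 10000, missing_rate = 0, seed = 11)
  co <- generate_cohort(cfg)
  expect_lt(abs(cor(co$data$treatment, co$true_class)), 0.05)
})

test_that("per-class per-arm mortality matches the closed-form logistic rates", {
  cfg <- generator_config(
    n_subjects = 5000, missing_rate = 0, seed = 21,
    mortality_base_logit = c(-1.25, -1.25),
    treatment_log_odds = c(-0.69, 0.69))
  co <- generate_cohort(cfg)
  for (k in 1:2) for (arm in 0:1) {
    sel <- co$true_class == k & co$data$treatment == arm
    p_true <- plogis(-1.25 + c(-0.69, 0.69)[k] * arm)
    mc_err <- 4 * sqrt(p_true * (1 - p_true) / sum(sel))
    expect_lt(abs(mean(co$data$death90[sel]) - p_true), mc_err)
  }
  # marginal mortality is the prevalence-weighted mixture of class rates
  p_marg <- sum(vapply(1:2, function(k)
    cfg$class_prevalence[k] * mean(plogis(-1.25 + c(-0.69, 0.69)[k] * c(0, 1))),
    numeric(1)))
  expect_lt(abs(mean(co$data$death90) - p_marg), 0.03)
})

test_that("default calibration reproduces ~22% vs ~45% control-arm mortality", {
  cfg <- generator_config(n_subjects = 1000, missing_rate = 0, seed = 5)
  co <- generate_cohort(cfg)
  ctrl <- co$data$treatment == 0
  m1 <- mean(co$data$death90[ctrl & co$true_class == 1])
  m2 <- mean(co$data$death90[ctrl & co$true_class == 2])
  expect_lt(abs(m1 - 0.221), 0.03)
  expect_lt(abs(m2 - 0.451), 0.06) # smaller class, wider MC error
})

test_that("null generator (no class signal) yields chance-level clustering and ~alpha HTE rejection", {
  fs <- default_feature_spec()
  fs$class_location <- I(lapply(fs$class_location, function(v) rep(v[1], 2)))
  rej <- 0; aris <- numeric(20)
  for (i in 1:20) {
    cfg <- generator_config(n_subjects = 400, feature_spec = fs,
                            mortality_base_logit = c(-1, -1),
                            treatment_log_odds = c(0, 0),
                            missing_rate = 0, seed = 100 + i)
    co <- generate_cohort(cfg)
    X <- scale(feature_matrix(co))
    km <- cluster_kmeans(X, 2, seed = i)
    aris[i] <- ari(km$labels, co$true_class)
    h <- interaction_lrt(co$data$death90, co$data$treatment, co$true_class)
    rej <- rej + h$significant
  }
  expect_lt(abs(mean(aris)), 0.05) # exchangeable: ARI ~ 0
  expect_lte(rej, 5)               # ~ alpha x 20 = 1 expected
})

test_that("missingness mechanisms behave as configured", {
  cfg <- generator_config(n_subjects = 1000, missing_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  expect_identical(apply_missingness(co, cfg), co) # rate 0: unchanged

  cfg10 <- generator_config(n_subjects = 1000, missing_rate = 0.1, seed = 3)
  co10 <- apply_missingness(co, cfg10)
  n_masked <- sum(is.na(co10$data$il6))
  expect_gte(n_masked, qbinom(0.005, 1000, 0.1))
  expect_lte(n_masked, qbinom(0.995, 1000, 0.1))
  expect_false(anyNA(co10$data$treatment))
  expect_false(anyNA(co10$data$death90))

  cfg_mar <- generator_config(n_subjects = 4000, missing_rate = 0.15,
                              missing_mechanism = "MAR", mar_driver = "age",
                              seed = 3)
  co_big <- generate_cohort(generator_config(n_subjects = 4000, seed = 3))
  co_mar <- apply_missingness(co_big, cfg_mar)
  masked <- is.na(co_mar$data$il6)
  expect_gt(mean(co_mar$data$age[masked]), mean(co_mar$data$age[!masked]))
})
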