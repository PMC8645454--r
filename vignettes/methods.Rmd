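---
title: "Methods: clustering randomised-trial subjects and testing for heterogeneity of treatment effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering randomised-trial subjects and testing for heterogeneity of treatment effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Critical-care trials randomise patients who meet broad syndromic criteria
(ARDS, sepsis), so a real benefit in one biological subgroup can be washed
out by harm or indifference in another. Heterogeneity of treatment effect
(HTE) is the non-random, explainable part of that variability.
`hteclust` implements a benchmark framework for the two-stage strategy used
to look for HTE in completed trials:

1. **Cluster** subjects on baseline partitioning variables — either
   *unsupervised* (blind to outcome and arm: latent class analysis,
   k-means, PAM, hierarchical, spectral) or *supervised* (trained on
   outcome and arm to predict individual treatment effects: X-learner,
   honest causal forest, model-based recursive partitioning).
2. **Test** the clusters for HTE: a likelihood-ratio test of the
   cluster-by-treatment interaction in a logistic model for 90-day
   mortality, with per-cluster odds ratios (OR > 1 = harm, < 1 = benefit,
   with death coded 1), plus a chi-squared test of outcome differences
   across clusters and gradient-boosting variable importance for cluster
   membership.

Because the trial datasets this design targets are access-restricted, the
package ships a synthetic RCT generator so that every stage is exercised
and tested end to end on data with *known* latent structure.

## The synthetic cohort: what it emulates

`generator_config()` defaults encode a two-subphenotype cohort of the kind
repeatedly reported for ARDS:

- **Prevalence 0.7 / 0.3** — a majority hypo-inflammatory class and a
  minority hyper-inflammatory class. Published analyses do not report the
  per-trial prevalences, so this is a calibration choice, fixed once.
- **Control-arm mortality ~22% vs ~45%** (`mortality_base_logit =
  qlogis(c(0.221, 0.451))`), calibrated to the two-class mortality split
  reported for the largest of the three trials the framework was designed
  around.
- **Opposite-direction treatment effects** (`treatment_log_odds =
  c(-0.69, +0.69)`, i.e. per-class ORs of about 0.5 and 2.0): the
  structure the framework is designed to detect — benefit in one class,
  harm in the other, near-null overall.
- **Class signal concentrated in biomarkers**: eight log-normal protein
  biomarker analogues (IL-6, IL-8, sTNFR-1, SP-D, PAI-1, ICAM-1, vWF,
  protein C) separated by 1.5 SD on the log scale, twelve clinical
  variables separated by only 0.3 SD, three binary covariates. This makes
  the biomarker-exclusion sensitivity analysis meaningful: removing the
  biomarkers removes most of the class signal.
- **Missingness**: MCAR at 5% per feature by default (a typical scale for
  baseline clinical variables), with a MAR option whose masking
  probability increases with a driver feature's rank. Treatment and
  outcome are never masked. MNAR is out of scope.

What the generator does **not** emulate: correlated feature blocks beyond
the class structure, survival-time outcomes, measurement error, or
informative missingness. Tests passing on this generator therefore show
that the *machinery* is correct and that the design's premise (detectable
HTE when clusters align with effect-modifying structure) holds under clean
conditions — not that any given algorithm will behave the same on real
trial data.

## Preprocessing

The fixed order is log-transform, impute, z-scale, applied exactly once
per run and recorded in a replayable `preprocess_state`:

- *Log transform*: "non-normally distributed" is operationalised as
  |sample skewness| > 1.0, with the metadata log-normal flag taking
  precedence so runs are deterministic. Non-positive values under a
  flagged transform are an error unless the `half_min_positive` offset
  policy is chosen (half the smallest positive value is added).
- *Imputation*: **single** imputation with chained equations — one
  completed dataset shared by all algorithms, not multiple imputation.
  Continuous features use predictive mean matching with a donor pool of
  5; binary features use a logistic draw; features are visited in order
  of increasing missingness for 10 cycles. The fixed cycle count is the
  stopping rule; the same seed always reproduces the same completed data.
- *Scaling*: continuous features to mean 0, SD 1 (n−1 convention). Binary
  features pass through unscaled: z-scaling 0/1 dummies would distort the
  Euclidean geometry the distance-based algorithms rely on.

## Cluster-number selection

**Distance-based algorithms** use consensus clustering: each algorithm is
re-run on resamples of 80% of subjects (feature subsampling optional),
and entry (i, j) of the consensus matrix is the fraction of co-sampled
resamples in which i and j co-clustered. The proportion of ambiguous
clustering (PAC) is the fraction of off-diagonal consensus values strictly
inside (0.1, 0.9); the K in 2..5 minimising PAC is selected, ties toward
smaller K. The resampling fractions and PAC band are standard choices; the
band endpoints are exposed as arguments. The paper-scale resample count is
B = 1000; the package default is B = 100, which the consensus literature
treats as adequate for stable PAC ordering — the full-scale setting is one
argument away.

**LCA** fits K = 1..Kmax by EM (Gaussian indicators with class-specific
variances — diagonal covariance, matching the conditional-independence
latent class model; Bernoulli indicators for binary features). Class
enumeration uses a parametric **bootstrap likelihood-ratio test** in place
of the VLMR test: the VLMR null distribution is non-standard and tied to a
specific commercial implementation, while the bootstrap LRT is
well-defined and serves the same role in the LCA literature. The selection
rule is sequential: accept K if the (K vs K−1) bootstrap p < 0.05, the
best log-likelihood replicated in ≥ 20 of the random starts (the
multi-start replication requirement), and the smallest class holds ≥ 5%
of subjects. BIC, relative entropy (1 − normalised posterior entropy) and
the smallest-class fraction are reported alongside.

Numerical choices: variance floor `1e-4` times each feature's marginal
variance; class-weight floor `1/(10 n)`; starts that still collapse are
discarded (an error only if all collapse). Bootstrap refits use a looser
EM tolerance (1e-6 relative) and a 100-iteration cap: the reference
distribution needs the LR statistic to roughly one decimal, not full
convergence, and this keeps enumeration tractable. LCA is fitted on the
single imputed dataset used by every other algorithm (not
full-information ML over missing cells) so that all algorithms see
identical inputs.

## The supervised arm

All three estimators see outcome and treatment — the mirror image of the
unsupervised contract — and every subject's effect estimate is
out-of-sample (5-fold cross-fitting stratified by arm-by-outcome; the
causal forest additionally supports out-of-bag prediction).

- **X-learner**: outcome surfaces fitted per arm, imputed individual
  effects regressed per arm, blended with the known trial propensity
  (0.5). Base learners are pluggable (random forest default via `ranger`,
  gradient boosting via `xgboost`, or any `function(X, y, seed)`); a BART
  adapter slot exists but is not shipped.
- **Causal forest**: honest trees — each tree's subsample is split into a
  half that chooses splits (maximising `n_L n_R (tau_L − tau_R)^2`, the
  between-child heterogeneity of the leaf effect) and a half that
  estimates leaf effects; leaves missing an arm inherit the parent
  estimate. This is a faithful implementation of the honest
  causal-forest idea, not a re-implementation of any specific package's
  internals.
- **MOB**: each node fits logistic `y ~ treatment`; parameter instability
  against each partitioning variable is tested with a permutation
  max-CUSUM statistic on the score contributions (199 permutations,
  Bonferroni across variables) in place of closed-form asymptotic
  fluctuation statistics; splits maximise the sum of child
  log-likelihoods over a 20-point quantile grid.

Effect estimates are risk differences (treated minus control); with death
as the outcome, `tau > 0` is the harm cluster and `tau < 0` the benefit
cluster. Exact zeros go to benefit by default and are flagged. If all
subjects land on one side, the assignment is a flagged single cluster and
the HTE test reports "not estimable" rather than failing.

## HTE evaluation

The interaction LRT compares logistic `y ~ cluster * w` against
`y ~ cluster + w` (largest cluster as reference level), statistic
`2 (LL_full − LL_reduced)` on K−1 df; p < 0.05 is the success criterion,
deliberately unadjusted across algorithms (the framework reports one test
per algorithm per dataset; the report records how many tests were run).
Any empty cluster-by-arm cell short-circuits to a flagged inestimable
result. Per-cluster odds ratios come from the within-cluster 2-by-2
tables with Wald CIs and a 0.5 continuity correction only when a cell is
zero (flagged); for saturated coding these equal the interaction-model
estimates, and both interpretations are documented in the output. Variable
importance is XGBoost split gain (200 trees, depth 3, eta 0.1, fixed for
reproducibility), normalised to shares summing to 1.

## Stability analysis

`run_replicates()` re-runs imputation *and* the clustering/ITE stage under
fresh seeds (10 runs by default), tests HTE per run, and reports the
pairwise adjusted Rand index matrix. The ARI is implemented from the
Hubert–Arabie pair-count formula and cross-checked in the tests against a
brute-force enumeration over all item pairs and against an independent
implementation. Seeds derive from the master seed through a splittable
multiplicative hash, so run i's seed never changes when more runs are
added. The mean ARI averages the off-diagonal pairs (the per-pair matrix
is also emitted since other aggregations are defensible). K is held fixed
across replicate runs at the value selected by the primary run —
re-selecting K in every replicate would confound cluster-composition
instability with selection instability, and the replicate analysis targets
the former. LCA replicates rely on the multi-start replication protocol
rather than a single seed, consistent with treating non-replicating LCA
solutions as unstable.

`biomarker_exclusion_run()` repeats the whole benchmark with
biomarker-flagged features dropped, everything else identical, to measure
how much HTE detection depends on them.

## Problem sizes and defaults used in the shipped tests

The test suite and acceptance script run the generator at its default
n = 1000 with consensus B = 100, bootstrap-LRT B = 49 (with 2–4 EM starts
per refit), 500 simulations for the power property, 1000 for the test-size
property, and 100 paired simulations for the biomarker-exclusion
direction. These sizes make the whole suite reproducible on a single CPU
in well under an hour while leaving the Monte-Carlo error comfortably
inside the asserted margins; every one of them is an argument, not a
constant.

## Known limitations

- The causal forest and MOB are compact reference implementations: no
  confidence intervals, no doubly-robust variants, no observational
  propensity estimation.
- Consensus feature subsampling defaults to off (100% of features);
  enabling it is one argument but its interaction with PAC calibration is
  the user's responsibility.
- LCA supports continuous and binary indicators; general categorical
  indicators enter as dummy-coded binaries.
- The generator's two-class default cannot stand in for cohorts with more
  classes, overlapping classes, or class-correlated missingness; supply a
  custom `feature_spec` for such designs.
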