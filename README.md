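# hteclust

Machine-learning clustering algorithms are increasingly used to hunt for
heterogeneity of treatment effect (HTE) in completed randomised controlled
trials: cluster the patients on baseline variables, then ask whether the
treatment effect differs across clusters. `hteclust` implements that whole
workflow as a tested, reusable R pipeline — five unsupervised clustering
algorithms, three supervised individual-treatment-effect estimators,
automated cluster-number selection, interaction-based HTE testing, variable
importance, and seed-perturbation stability analysis — together with a
synthetic RCT generator so everything runs and is verifiable without
access-restricted trial data.

It is aimed at biostatisticians and critical-care researchers doing
secondary analyses of RCTs (e.g. ARDS or sepsis trials) who want to
benchmark clustering strategies before trusting a subgroup claim.

## What it computes

**Clustering.** Unsupervised, blind to outcome and arm: latent class /
profile analysis by EM with multi-start (class-specific diagonal
covariances, Bernoulli indicators for binaries), k-means (Lloyd +
k-means++), PAM (BUILD/SWAP), Ward hierarchical, and spectral clustering
(normalised Laplacian, Ng–Jordan–Weiss). Supervised, trained on outcome
`y` and arm `w` to estimate per-subject effects
`tau(x) = P(y=1 | w=1, x) − P(y=1 | w=0, x)`: X-learner, honest causal
forest, and model-based recursive partitioning (MOB); subjects are
dichotomised into benefit (`tau < 0`) and harm (`tau > 0`) clusters.

**Cluster number.** Distance-based algorithms: consensus clustering over
subject resamples, choosing K in 2..5 to minimise the proportion of
ambiguous clustering, PAC = fraction of consensus entries in (0.1, 0.9).
LCA: sequential parametric bootstrap likelihood-ratio tests (K vs K−1),
requiring the best log-likelihood to replicate in ≥ 20 random starts and
the smallest class to hold ≥ 5% of subjects, with BIC and relative entropy
reported.

**HTE testing.** For each clustering, a likelihood-ratio test of the
interaction in logistic `y ~ cluster * w` versus `y ~ cluster + w`
(statistic `2ΔLL ~ χ²(K−1)`; p < 0.05 = HTE), per-cluster treatment odds
ratios (death coded 1, so OR > 1 = harm), a chi-squared test of mortality
across clusters, and XGBoost gain-based variable importance for cluster
membership.

**Stability.** `run_replicates()` reruns imputation and clustering under
10 fresh seeds and summarises agreement with the adjusted Rand index
(Hubert–Arabie); `biomarker_exclusion_run()` repeats the benchmark without
protein biomarkers.

## Worked example

```r
library(hteclust)

cfg <- run_config(
  input      = generator_config(n_subjects = 1000, seed = 101),
  algorithms = c("lca", "kmeans", "causal_forest"),
  master_seed = 2024)
bundle <- run_benchmark(cfg)
bundle
#> <benchmark_bundle> 1000 subjects, 3 algorithm(s), ...
#>  algorithm K     lrt_p significant
#>        lca 2 1.351e-05        TRUE
#>     kmeans 2 6.651e-05        TRUE
#> causal_forest 2 3.686e-03      TRUE

ari(bundle$results$lca$assignment$labels, bundle$cohort$true_class)
#> ~0.9  (LCA recovers the generator's two subphenotypes)

head(bundle$results$lca$importance, 3)
#> biomarker analogues (sTNFR-1, SP-D, IL-6, ...) dominate the gain shares
```

The generator's defaults encode a two-subphenotype cohort (70/30 split,
control-arm mortality ≈ 22% vs 45%, treatment log-odds −0.69 in class 1
and +0.69 in class 2, class signal concentrated in eight log-normal
biomarkers). The LCA and k-means clusters align with the latent classes,
so their interaction tests reject: the benefit cluster's OR is ≈ 0.5 and
the harm cluster's ≈ 2. A `run_config(..., stability = TRUE)` run adds the
10-seed replicate analysis per algorithm.

Full methodological details — model assumptions, selection rules, numeric
floors and tolerances, and what the synthetic generator does and does not
emulate — are in `vignettes/methods.Rmd`.

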