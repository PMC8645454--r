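# shared fixtures and independent oracles, all built in code

# n_per points around each center (rows of `centers`), isotropic gaussian
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# tiny hand-built cohort for IO / preprocessing tests
make_tiny_cohort <- function(n = 5, missing = FALSE) {
  set.seed(42)
  dat <- data.frame(
    subject_id = paste0("P", seq_len(n)),
    treatment = rep_len(c(0L, 1L), n),
    death90 = rep_len(c(0L, 0L, 1L), n),
    il6 = exp(rnorm(n, 4)),
    age = round(rnorm(n, 55, 10), 1),
    sex_male = rep_len(c(1L, 0L), n)
  )
  meta <- data.frame(
    name = c("il6", "age", "sex_male"),
    type = c("continuous", "continuous", "binary"),
    is_biomarker = c(TRUE, FALSE, FALSE),
    lognormal = c(TRUE, FALSE, FALSE)
  )
  if (missing) {
    dat$il6[2] <- NA
    dat$age[c(1, 4)] <- NA
  }
  new_cohort(dat, meta)
}

# brute-force ARI over all C(n,2) item pairs (independent of ari())
ari_bruteforce <- function(a, b, pairs = utils::combn(length(a), 2)) {
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  total <- ncol(pairs)
  index <- sum(sa & sb)
  expected <- sum(sa) * sum(sb) / total
  maxi <- (sum(sa) + sum(sb)) / 2
  if (maxi - expected == 0) return(1.0)
  (index - expected) / (maxi - expected)
}

# all set partitions of n items into at most max_blocks blocks, as
# restricted growth strings
all_partitions <- function(n, max_blocks = 3L) {
  out <- list()
  rec <- function(labels, next_block) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (b in seq_len(min(next_block, max_blocks))) {
      rec(c(labels, b), max(next_block, b + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# independent LRT oracle: maximise the binomial log-likelihood of the
# cluster x arm x outcome table directly with optim (full model via the
# saturated cell means, reduced model via a 3-parameter logistic)
lrt_oracle_2x2x2 <- function(deaths, totals) {
  # deaths/totals: 2x2 matrices [cluster, arm]
  ll_sat <- sum(mapply(function(d, m) {
    p <- d / m
    stats::dbinom(d, m, p, log = TRUE)
  }, deaths, totals))
  nll_red <- function(theta) {
    # theta: intercept, cluster2, treatment
    lp <- outer(c(0, theta[2]), c(0, theta[3]), "+") + theta[1]
    -sum(stats::dbinom(deaths, totals, stats::plogis(lp), log = TRUE))
  }
  opt <- stats::optim(c(0, 0, 0), nll_red, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  stat <- 2 * (ll_sat + opt$value)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# expand a 2x2x2 table into subject-level vectors
expand_2x2x2 <- function(deaths, totals) {
  y <- w <- cl <- integer(0)
  for (k in 1:2) for (arm in 0:1) {
    m <- totals[k, arm + 1]
    d <- deaths[k, arm + 1]
    y <- c(y, rep(1L, d), rep(0L, m - d))
    w <- c(w, rep(arm, m))
    cl <- c(cl, rep(k, m))
  }
  list(y = y, w = w, cluster = cl)
}
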