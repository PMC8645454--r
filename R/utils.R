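#' Derive a child seed from a master seed
#'
#' Splittable seed derivation: run `index` (and optional `stream`) map to a
#' child seed through a Lehmer-style multiplicative hash, so each child
#' depends only on `(master_seed, index, stream)`. Adding later runs never
#' changes the seeds of earlier ones.
#'
#' @param master_seed integer master seed.
#' @param index integer run/stage index (0, 1, 2, ...).
#' @param stream optional integer sub-stream discriminator.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index, stream = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  m <- 2147483647 # 2^31 - 1 (Mersenne prime modulus)
  a <- 48271
  x <- (abs(as.double(master_seed)) %% m)
  x <- (x + as.double(index) * 104729 + as.double(stream) * 7919) %% m
  # three rounds of a*x mod m; a*x < 1.04e14 stays exact in doubles
  for (i in 1:3) x <- (a * x) %% m
  as.integer(x %% (m - 1) + 1)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# sample skewness g1 = m3 / m2^(3/2)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# log-sum-exp over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# squared Euclidean distances between rows of X (n x p) and C (k x p)
sqdist_to_centers <- function(X, C) {
  n2x <- rowSums(X^2)
  n2c <- rowSums(C^2)
  d <- outer(n2x, n2c, "+") - 2 * tcrossprod(X, C)
  d[d < 0] <- 0
  d
}
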