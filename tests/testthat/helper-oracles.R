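# Independent oracles kept deliberately separate from the implementation.

# Exhaustive-enumeration k-means oracle: optimal WCSS over all assignments of
# n points to at most k clusters (feasible for n <= 9, k <= 3).
brute_force_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 9, k <= 3)
  asn <- rep(1L, n)
  best <- Inf
  repeat {
    w <- 0
    for (c in unique(asn)) {
      xs <- x[asn == c, , drop = FALSE]
      w <- w + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    if (w < best) best <- w
    # next assignment in base-k counting
    i <- 1L
    while (i <= n && asn[i] == k) {
      asn[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    asn[i] <- asn[i] + 1L
  }
  best
}

# Count circular local maxima of a single-breath waveform.
circular_maxima <- function(x) {
  n <- length(x)
  xl <- c(x[n], x, x[1])
  d <- diff(xl)
  sum(d[1:n] > 0 & d[2:(n + 1)] <= 0)
}

# Adjusted Rand index via mclust (independent of the package under test).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Reference FPCA via prcomp on the discretized curves (the brute-force PCA
# equivalence oracle): eigenvalues and scores in the dt-weighted convention.
prcomp_fpca_oracle <- function(curves, dt = 0.1) {
  pc <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
  list(lambda = pc$sdev^2 * dt,
       scores = pc$x * sqrt(dt),
       rotation = pc$rotation / sqrt(dt))
}
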