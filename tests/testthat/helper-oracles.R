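# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# LZ76 exhaustive-history parse count by direct definition: repeatedly find
# the longest prefix of the remainder that occurs as a substring of the
# already-seen text extended up to (but not including) the phrase end
# (overlapping copies allowed), then add one innovative symbol.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  pos <- 1
  c_cnt <- 0L
  while (pos <= n) {
    len <- 0
    # longest L such that substr(pos, pos+L-1) occurs starting before pos
    while (pos + len <= n) {
      pat <- substr(s, pos, pos + len)
      hist <- substr(s, 1, pos + len)   # copy source must start before pos
      found <- FALSE
      for (st in seq_len(pos - 1)) {
        if (substr(hist, st, st + len) == pat) { found <- TRUE; break }
      }
      if (!found) break
      len <- len + 1
    }
    pos <- pos + len + 1                # longest copy plus one new symbol
    c_cnt <- c_cnt + 1L
  }
  c_cnt
}

# Spectral radius via power iteration on a nonnegative matrix (Perron
# root), independent of eigen().
power_radius <- function(A, iters = 500) {
  v <- rep(1, nrow(A))
  lambda <- 0
  for (i in seq_len(iters)) {
    w <- A %*% v
    lambda <- sqrt(sum(w^2))
    if (lambda == 0) return(0)
    v <- as.vector(w / lambda)
  }
  lambda
}

# Fixed-point iteration for the stationary covariance.
lyapunov_iterate <- function(A, Q, iters = 10000, tol = 1e-14) {
  S <- Q
  for (i in seq_len(iters)) {
    S_new <- A %*% S %*% t(A) + Q
    if (max(abs(S_new - S)) < tol) return(S_new)
    S <- S_new
  }
  S
}

# Random stable lagged Gaussian model built from a random AR(1) system.
random_lagged_model <- function(n, noise_corr = NULL) {
  A <- matrix(rnorm(n * n, sd = 0.4 / sqrt(n)), n, n)
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr >= 0.95) A <- A * 0.9 / sr
  cc <- if (is.null(noise_corr)) runif(1, 0, 0.6) else noise_corr
  Q <- matrix(cc, n, n); diag(Q) <- 1
  net <- structure(list(A = A, noise_corr = cc, noise_cov = Q),
                   class = "ar_network")
  ar_lagged_gaussian(net, tau = 1)
}

random_bipartition <- function(n) {
  k <- sample(seq_len(n - 1), 1)
  S <- sort(sample.int(n, k))
  list(S, setdiff(seq_len(n), S))
}

# Gaussian log-density used by the Monte-Carlo entropy oracle.
dmvnorm_log <- function(x, S) {
  k <- ncol(x)
  L <- chol(S)
  z <- forwardsolve(t(L), t(x))
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(L))) / 1) - 0.5 * colSums(z^2)
}
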