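#' Configuration for the random autoregressive network ensemble
#'
#' Defines the generative ensemble of first-order autoregressive (AR)
#' networks used in the simulation study: `n_nodes` coupled units whose
#' off-diagonal weights are drawn from a Beta distribution with shape
#' parameters themselves drawn uniformly per network, self-connections set
#' to a random multiple of each row's median outgoing weight, and additive
#' equicorrelated Gaussian innovations. Only weight matrices with spectral
#' radius below one (stationary dynamics) are accepted.
#'
#' @param n_nodes Number of network nodes (default 8).
#' @param alpha_range,beta_range Intervals from which the Beta shape
#'   parameters `alpha` and `beta` are drawn uniformly, once per network.
#' @param diag_scale_range Interval for the self-connection multiplier `r`:
#'   the diagonal of the weight matrix is `r` times the median of that
#'   row's off-diagonal (outgoing) weights.
#' @param noise_corr_range Interval for the shared innovation correlation
#'   `c`; the innovation covariance has unit diagonal and all off-diagonal
#'   entries equal to `c`.
#' @param steps Number of simulation steps per network.
#' @param n_networks Number of networks in the ensemble.
#' @param max_attempts Rejection-sampling cap per network; exceeding it is
#'   an error ("unrealizable configuration").
#' @return An object of class `ar_config`.
#' @export
ar_config <- function(n_nodes = 8,
                      alpha_range = c(0.001, 10.1),
                      beta_range = c(0.001, 10.1),
                      diag_scale_range = c(3, 6),
                      noise_corr_range = c(0, 1),
                      steps = 10000,
                      n_networks = 1670,
                      max_attempts = 10000) {
  stopifnot(n_nodes >= 1, steps >= 2, n_networks >= 1, max_attempts >= 1)
  check_range <- function(r, name) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid range for ", name)
  }
  check_range(alpha_range, "alpha_range")
  check_range(beta_range, "beta_range")
  check_range(diag_scale_range, "diag_scale_range")
  check_range(noise_corr_range, "noise_corr_range")
  if (n_nodes >= 2 && steps < 10 * n_nodes)
    stop("steps must be at least 10 * n_nodes")
  structure(list(n_nodes = n_nodes,
                 alpha_range = alpha_range,
                 beta_range = beta_range,
                 diag_scale_range = diag_scale_range,
                 noise_corr_range = noise_corr_range,
                 steps = steps,
                 n_networks = n_networks,
                 max_attempts = max_attempts),
            class = "ar_config")
}

#' Spectral radius of a square matrix
#' @param A Square numeric matrix.
#' @return Largest eigenvalue modulus.
#' @export
spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Sample one autoregressive network from the ensemble
#'
#' Draws candidate weight matrices until one has spectral radius strictly
#' below one. Off-diagonal weights are i.i.d. Beta(alpha, beta) with the
#' shapes drawn once per candidate; each diagonal entry is `r` times the
#' median of the row's off-diagonal weights (midpoint median for even
#' counts); the innovation covariance is the equicorrelation matrix with
#' unit variances and correlation `c`.
#'
#' @param config An [ar_config()].
#' @return An object of class `ar_network` with elements `A` (weights),
#'   `noise_corr` (`c`), `noise_cov`, `diag_scale` (`r`), `alpha`, `beta`,
#'   and `attempts` (number of candidates drawn, accepted one included).
#' @export
sample_ar_network <- function(config) {
  stopifnot(inherits(config, "ar_config"))
  n <- config$n_nodes
  for (attempt in seq_len(config$max_attempts)) {
    alpha <- runif(1, config$alpha_range[1], config$alpha_range[2])
    beta <- runif(1, config$beta_range[1], config$beta_range[2])
    r <- runif(1, config$diag_scale_range[1], config$diag_scale_range[2])
    cc <- runif(1, config$noise_corr_range[1], config$noise_corr_range[2])
    A <- matrix(0, n, n)
    if (n > 1) {
      off <- matrix(rbeta(n * (n - 1), alpha, beta), n, n - 1)
      for (i in seq_len(n)) {
        A[i, -i] <- off[i, ]
        A[i, i] <- r * median(off[i, ])
      }
    }
    # n == 1 keeps A = 0: the single node has no outgoing weights
    if (spectral_radius(A) < 1) {
      noise_cov <- matrix(cc, n, n)
      diag(noise_cov) <- 1
      return(structure(list(A = A, noise_corr = cc, noise_cov = noise_cov,
                            diag_scale = r, alpha = alpha, beta = beta,
                            attempts = attempt),
                       class = "ar_network"))
    }
  }
  stop("unrealizable configuration: no stable network within max_attempts")
}

#' Simulate an autoregressive network
#'
#' Iterates `X[t+1] = A X[t] + eps[t]` from an all-zero initial state, with
#' `eps[t]` i.i.d. multivariate normal with covariance `net$noise_cov`.
#'
#' @param net An `ar_network`.
#' @param steps Number of time steps to produce.
#' @return Numeric matrix, nodes x steps.
#' @export
simulate_ar <- function(net, steps) {
  stopifnot(inherits(net, "ar_network"), steps >= 2)
  n <- nrow(net$A)
  L <- t(chol(net$noise_cov))
  eps <- L %*% matrix(rnorm(n * steps), n, steps)
  X <- matrix(0, n, steps)
  x <- numeric(n)
  A <- net$A
  for (t in seq_len(steps)) {
    x <- drop(A %*% x) + eps[, t]
    X[, t] <- x
  }
  if (!all(is.finite(X))) stop("non-finite state encountered during simulation")
  X
}

#' Stationary covariance of an autoregressive network
#'
#' Solves the discrete Lyapunov equation `S = A S A' + Q` (with `Q` the
#' innovation covariance) by vectorization, giving the covariance of the
#' stationary process. Requires spectral radius of `A` below one.
#'
#' @param net An `ar_network`.
#' @return Symmetric positive semidefinite matrix, nodes x nodes.
#' @export
stationary_covariance <- function(net) {
  stopifnot(inherits(net, "ar_network"))
  A <- net$A
  if (spectral_radius(A) >= 1) stop("invalid network: spectral radius >= 1")
  n <- nrow(A)
  S <- solve(diag(n * n) - kronecker(A, A), as.vector(net$noise_cov))
  S <- matrix(S, n, n)
  (S + t(S)) / 2
}
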