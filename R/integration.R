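# Gaussian-approximation integrated-information measures.
#
# All measures operate on a lagged Gaussian model of a stationary
# multichannel signal: the joint distribution of the state X at time t - tau
# ("past") and t ("present") is approximated as a zero-mean Gaussian with
# equal-time covariances cov_x, cov_y and cross-covariance
# cov_xy = E[past %*% t(present)]. Entropies and informations are in nats.

logdet <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) stop("matrix is not positive definite")
  as.numeric(d$modulus)
}

gauss_entropy <- function(S) {
  k <- nrow(S)
  0.5 * (k * log(2 * pi * exp(1)) + logdet(S))
}

#' Fit a lagged Gaussian model to multichannel data
#'
#' Estimates the equal-time and time-lagged covariances of a channels x
#' samples matrix at lag `tau`. If the stacked 2n x 2n joint covariance is
#' not positive definite, a ridge is added to its diagonal, escalating
#' through `ridge_ladder` until it is; the ridge used is recorded.
#'
#' @param x Numeric matrix, channels x samples.
#' @param tau Lag in samples (default 1).
#' @param ridge_ladder Increasing ridge values to try when the joint
#'   covariance is numerically singular.
#' @return An object of class `lagged_gaussian` with fields `cov_x`,
#'   `cov_y`, `cov_xy`, `tau`, `n`, `ridge`.
#' @export
fit_lagged_gaussian <- function(x, tau = 1,
                                ridge_ladder = 10^seq(-12, -6, by = 1)) {
  stopifnot(is.matrix(x), tau >= 1, ncol(x) > tau)
  n <- nrow(x)
  if (ncol(x) - tau < 10 * n)
    stop("need at least 10 x channels effective samples")
  past <- t(x[, seq_len(ncol(x) - tau), drop = FALSE])
  pres <- t(x[, (tau + 1):ncol(x), drop = FALSE])
  cov_x <- cov(past)
  cov_y <- cov(pres)
  cov_xy <- cov(past, pres)
  ridge <- 0
  for (eps in c(0, ridge_ladder)) {
    joint <- rbind(cbind(cov_x, cov_xy), cbind(t(cov_xy), cov_y)) +
      diag(eps, 2 * n)
    ok <- tryCatch({ chol(joint); TRUE }, error = function(e) FALSE)
    if (ok) { ridge <- eps; break }
    if (eps == max(ridge_ladder))
      stop("joint covariance rank-deficient even after maximal ridge")
  }
  structure(list(cov_x = cov_x + diag(ridge, n),
                 cov_y = cov_y + diag(ridge, n),
                 cov_xy = cov_xy, tau = tau, n = n, ridge = ridge),
            class = "lagged_gaussian")
}

#' Construct a lagged Gaussian model from known covariances
#'
#' @param cov_x,cov_y Equal-time covariances of past and present states
#'   (for a stationary process these coincide; `cov_y` defaults to `cov_x`).
#' @param cov_xy Cross-covariance `E[past %*% t(present)]`.
#' @param tau Lag in samples.
#' @return A `lagged_gaussian` object.
#' @export
lagged_gaussian <- function(cov_x, cov_xy, cov_y = cov_x, tau = 1) {
  stopifnot(is.matrix(cov_x), all(dim(cov_x) == dim(cov_xy)),
            all(dim(cov_x) == dim(cov_y)))
  structure(list(cov_x = cov_x, cov_y = cov_y, cov_xy = cov_xy,
                 tau = tau, n = nrow(cov_x), ridge = 0),
            class = "lagged_gaussian")
}

#' Lagged Gaussian model implied by an autoregressive network
#'
#' Analytic counterpart of [fit_lagged_gaussian()] on simulated data: the
#' stationary covariance solves the Lyapunov equation and the lag-tau
#' cross-covariance is `S %*% t(A)^tau`.
#'
#' @param net An `ar_network`.
#' @param tau Lag in samples.
#' @return A `lagged_gaussian` object.
#' @export
ar_lagged_gaussian <- function(net, tau = 1) {
  S <- stationary_covariance(net)
  At <- diag(nrow(S))
  for (i in seq_len(tau)) At <- At %*% t(net$A)
  lagged_gaussian(cov_x = S, cov_xy = S %*% At, cov_y = S, tau = tau)
}

sub_model <- function(model, idx) {
  lagged_gaussian(cov_x = model$cov_x[idx, idx, drop = FALSE],
                  cov_xy = model$cov_xy[idx, idx, drop = FALSE],
                  cov_y = model$cov_y[idx, idx, drop = FALSE],
                  tau = model$tau)
}

check_partition <- function(partition, n) {
  idx <- sort(unlist(partition))
  if (!identical(as.integer(idx), seq_len(n)) || length(partition) < 2 ||
      any(lengths(partition) == 0))
    stop("partition must be >= 2 disjoint non-empty blocks covering 1..n")
  lapply(partition, as.integer)
}

#' Multi-information (total equal-time correlation)
#'
#' `sum_i h(X_i) - h(X)` under the Gaussian model; zero iff the equal-time
#' covariance is diagonal.
#'
#' @param model A `lagged_gaussian`.
#' @return Nats (nonnegative).
#' @export
multi_information <- function(model) {
  S <- model$cov_x
  val <- 0.5 * (sum(log(diag(S))) - logdet(S))
  max(val, 0)
}

lagged_mi <- function(model) {
  joint <- rbind(cbind(model$cov_x, model$cov_xy),
                 cbind(t(model$cov_xy), model$cov_y))
  0.5 * (logdet(model$cov_x) + logdet(model$cov_y) - logdet(joint))
}

#' Total time-lagged mutual information of the model
#'
#' `I(X_past; X_present)` in nats.
#' @param model A `lagged_gaussian`.
#' @return Nats.
#' @export
total_lagged_mi <- function(model) lagged_mi(model)

#' Mutual integrated information (MII)
#'
#' Whole-system lagged mutual information minus the sum of within-block
#' lagged mutual informations. Can be negative when the parts are
#' individually more self-predictive than the whole.
#'
#' @param model A `lagged_gaussian`.
#' @param partition List of integer vectors: disjoint blocks covering all
#'   channels.
#' @return Nats.
#' @export
mii <- function(model, partition) {
  partition <- check_partition(partition, model$n)
  lagged_mi(model) - sum(vapply(partition, function(idx)
    lagged_mi(sub_model(model, idx)), numeric(1)))
}

cond_entropy <- function(model) {
  # h(present | past) = h(joint) - h(past)
  joint <- rbind(cbind(model$cov_x, model$cov_xy),
                 cbind(t(model$cov_xy), model$cov_y))
  gauss_entropy(joint) - gauss_entropy(model$cov_x)
}

#' Stochastic interaction (SI)
#'
#' Excess of the summed within-block conditional entropies
#' `h(present_k | past_k)` over the whole-system conditional entropy; always
#' nonnegative and an upper bound on geometric integrated information.
#'
#' @inheritParams mii
#' @return Nats (nonnegative).
#' @export
stochastic_interaction <- function(model, partition) {
  partition <- check_partition(partition, model$n)
  val <- sum(vapply(partition, function(idx)
    cond_entropy(sub_model(model, idx)), numeric(1))) - cond_entropy(model)
  max(val, 0)
}

# Block-diagonal mismatched decoder: regression and residual covariance of
# each block in isolation, embedded in full coordinates.
mismatched_decoder <- function(model, partition) {
  n <- model$n
  A_d <- matrix(0, n, n)     # maps past to predicted present
  S_d <- matrix(0, n, n)     # block residual covariance
  for (idx in partition) {
    sm <- sub_model(model, idx)
    Ak <- t(sm$cov_xy) %*% solve(sm$cov_x)
    A_d[idx, idx] <- Ak
    S_d[idx, idx] <- sm$cov_y - Ak %*% sm$cov_xy
  }
  list(A = A_d, S = S_d)
}

# Mismatched-decoding information curve I~(beta) for the Gaussian model and
# a block-factorized decoder (closed form; derivation via the Gaussian
# integral of q(Y|X)^beta over p(X)).
phi_star_curve <- function(model, decoder) {
  Sx <- model$cov_x
  Sy <- model$cov_y
  Sxy <- model$cov_xy
  A_d <- decoder$A
  Sd_inv <- solve(decoder$S)
  B <- t(A_d) %*% Sd_inv %*% A_d
  cross <- t(Sxy) %*% t(A_d)                # Sigma_yx A_d'
  lin <- sum(Sd_inv * (cross + t(cross) - A_d %*% Sx %*% t(A_d)))
  G <- t(A_d) %*% Sd_inv %*% Sy %*% Sd_inv %*% A_d
  Sx_inv <- solve(Sx)
  n <- model$n
  function(beta) {
    M <- diag(n) + beta * (Sx %*% B)
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0) return(-Inf)
    0.5 * (beta * lin + as.numeric(d$modulus) -
             beta^2 * sum(solve(Sx_inv + beta * B) * G))
  }
}

#' Decoder-based integrated information (phi-star)
#'
#' Loss of predictive information when decoding the present from the past
#' with a block-factorized (mismatched) decoder, maximized over the scalar
#' decoding parameter beta by one-dimensional numerical optimization.
#' Satisfies `0 <= phi_star <= I(past; present)`.
#'
#' @inheritParams mii
#' @param beta_max Upper end of the beta search interval.
#' @param tol Optimizer tolerance.
#' @return List with `value` (nats), `beta` (maximizing decoding parameter),
#'   and `mi` (total lagged mutual information).
#' @export
phi_star <- function(model, partition, beta_max = 20, tol = 1e-7) {
  partition <- check_partition(partition, model$n)
  I <- lagged_mi(model)
  curve <- phi_star_curve(model, mismatched_decoder(model, partition))
  opt <- optimize(curve, interval = c(0, beta_max), maximum = TRUE, tol = tol)
  istar <- max(opt$objective, 0)            # beta = 0 gives I~ = 0
  val <- min(max(I - istar, 0), I)
  list(value = val, beta = opt$maximum, mi = I)
}

# Residual covariance of the present given the past under regression map A
# (present_hat = A past).
phig_residual <- function(A, Sx, Sxy, Sy) {
  cross <- t(Sxy) %*% t(A)
  Sy - cross - t(cross) + A %*% Sx %*% t(A)
}

#' Geometric integrated information (phi-G)
#'
#' Minimal Kullback-Leibler divergence from the fitted lagged Gaussian to
#' the manifold of models with no cross-block lagged influence: the
#' past-to-present regression matrix is constrained to be block diagonal
#' with respect to the partition while the equal-time structure and the
#' residual covariance remain free. With the residual covariance
#' moment-matched, the divergence reduces to
#' `0.5 * (logdet M(A) - logdet Sigma_E)` where `M(A)` is the residual
#' covariance under the constrained regression `A` and `Sigma_E` the
#' unconstrained one. The constrained `A` is found by a damped
#' fixed-point iteration on the stationarity condition (a linear solve per
#' iteration), with a BFGS fallback.
#'
#' @inheritParams mii
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the objective.
#' @return List with `value` (nats, nonnegative) and `A` (constrained
#'   regression matrix).
#' @export
phi_g <- function(model, partition, max_iter = 100, tol = 1e-10) {
  partition <- check_partition(partition, model$n)
  n <- model$n
  Sx <- model$cov_x; Sxy <- model$cov_xy; Sy <- model$cov_y
  Syx <- t(Sxy)
  A_full <- Syx %*% solve(Sx)
  S_e <- phig_residual(A_full, Sx, Sxy, Sy)
  ld_e <- logdet(S_e)

  mask <- matrix(FALSE, n, n)
  for (idx in partition) mask[idx, idx] <- TRUE
  free <- which(mask)

  obj <- function(A) logdet(phig_residual(A, Sx, Sxy, Sy))

  # start from the block-truncated full regression
  A <- A_full * mask
  f <- obj(A)
  # Stationarity: [M(A)^-1 (A Sx - Syx)]_free = 0. Given M, this is linear
  # in the free entries of A; iterate with step damping if the objective
  # would increase.
  K <- kronecker(t(Sx), diag(n))            # vec(A Sx) = K vec(A)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Minv <- solve(phig_residual(A, Sx, Sxy, Sy))
    KM <- kronecker(t(Sx), Minv)            # vec(Minv A Sx) = KM vec(A)
    rhs <- as.vector(Minv %*% Syx)[free]
    A_new <- matrix(0, n, n)
    A_new[free] <- solve(KM[free, free, drop = FALSE], rhs)
    step <- 1
    repeat {
      A_try <- A + step * (A_new - A)
      f_try <- tryCatch(obj(A_try), error = function(e) Inf)
      if (f_try <= f + 1e-14 || step < 1e-6) break
      step <- step / 2
    }
    if (!is.finite(f_try)) break
    delta <- f - f_try
    A <- A_try; f <- f_try
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    # quasi-Newton fallback on the free entries
    gr <- function(par) {
      A[free] <- par
      Minv <- solve(phig_residual(A, Sx, Sxy, Sy))
      (2 * (Minv %*% (A %*% Sx - Syx)))[free]
    }
    fn <- function(par) { A[free] <- par; obj(A) }
    opt <- optim(A[free], fn, gr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    if (opt$value < f) { A[free] <- opt$par; f <- opt$value }
  }
  list(value = max(0.5 * (f - ld_e), 0), A = A)
}

#' Evaluate an integrated-information measure on a bipartition
#'
#' Thin dispatcher used by the partition searches.
#'
#' @param model A `lagged_gaussian`.
#' @param partition List of blocks.
#' @param measure One of `"phi_g"`, `"phi_star"`, `"si"`, `"mii"`.
#' @return Numeric value in nats.
#' @export
phi_measure <- function(model, partition,
                        measure = c("phi_g", "phi_star", "si", "mii")) {
  measure <- match.arg(measure)
  switch(measure,
         phi_g = phi_g(model, partition)$value,
         phi_star = phi_star(model, partition)$value,
         si = stochastic_interaction(model, partition),
         mii = mii(model, partition))
}
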