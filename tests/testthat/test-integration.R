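joint_cov <- function(m) {
  rbind(cbind(m$cov_x, m$cov_xy), cbind(t(m$cov_xy), m$cov_y))
}

test_that("lagged Gaussian fits recover known structure", {
  set.seed(40)
  x <- matrix(rnorm(4 * 20000), 4)
  m <- fit_lagged_gaussian(x)
  expect_lt(max(abs(m$cov_x - diag(4))), 0.05)
  expect_lt(max(abs(m$cov_xy)), 0.05)
  # scalar AR(1), a = 0.5: lag-1 autocovariance over variance equals a
  a <- 0.5
  x1 <- as.numeric(stats::filter(rnorm(50000), a, method = "recursive"))
  m1 <- fit_lagged_gaussian(rbind(x1, rnorm(50000)), tau = 1)
  expect_equal(m1$cov_xy[1, 1] / m1$cov_x[1, 1], a, tolerance = 0.03)
  # simulated network matches the Lyapunov solution and S %*% t(A)
  net <- sample_ar_network(ar_config())
  X <- simulate_ar(net, 50000)
  mf <- fit_lagged_gaussian(X[, 5001:50000])
  S <- stationary_covariance(net)
  expect_lt(max(abs(mf$cov_x - S)) / max(abs(S)), 0.1)
  expect_lt(max(abs(mf$cov_xy - S %*% t(net$A))) / max(abs(S)), 0.1)
})

test_that("multi-information has its Gaussian closed forms", {
  m <- lagged_gaussian(cov_x = diag(3), cov_xy = matrix(0, 3, 3))
  expect_equal(multi_information(m), 0)
  r <- 0.5
  S <- matrix(c(1, r, r, 1), 2)
  m2 <- lagged_gaussian(cov_x = S, cov_xy = matrix(0, 2, 2))
  expect_equal(multi_information(m2), -0.5 * log(1 - r^2))
  # invariant under channel-wise rescaling
  D <- diag(c(3, 0.2))
  m3 <- lagged_gaussian(cov_x = D %*% S %*% D, cov_xy = matrix(0, 2, 2))
  expect_equal(multi_information(m3), multi_information(m2))
})

test_that("MII vanishes on independent blocks and reduces to whole-system MI", {
  set.seed(41)
  # two independent 2-node AR blocks
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- matrix(c(.5, .2, .1, .4), 2)
  A[3:4, 3:4] <- matrix(c(.3, .1, .2, .5), 2)
  Q <- diag(4)
  net <- structure(list(A = A, noise_cov = Q), class = "ar_network")
  m <- ar_lagged_gaussian(net)
  expect_equal(mii(m, list(1:2, 3:4)), 0, tolerance = 1e-10)
  # purely cross-predictive system: parts have zero self-predictability, so
  # MII equals the whole-system lagged MI
  cx <- matrix(c(0, .4, .3, 0), 2)
  mc <- lagged_gaussian(cov_x = diag(2), cov_xy = cx)
  expect_equal(mii(mc, list(1, 2)), total_lagged_mi(mc))
  # a shared source across blocks makes MII positive
  As <- matrix(0.3, 2, 2)
  nets <- structure(list(A = As, noise_cov = diag(2)), class = "ar_network")
  expect_gt(mii(ar_lagged_gaussian(nets), list(1, 2)), 0)
})

test_that("stochastic interaction matches a Monte-Carlo entropy oracle", {
  set.seed(42)
  A <- matrix(c(.5, .3, .2, .4), 2)
  net <- structure(list(A = A, noise_cov = diag(2)), class = "ar_network")
  m <- ar_lagged_gaussian(net)
  part <- list(1, 2)
  si <- stochastic_interaction(m, part)
  # oracle: H(Y_k | X_k) - H(Y | X) from Gaussian log densities evaluated
  # on samples drawn from the analytic joint (law of large numbers)
  J <- joint_cov(m)
  N <- 2e5
  Z <- matrix(rnorm(N * 4), N) %*% chol(J)
  h_pair <- function(cols_joint, cols_marg) {
    -mean(dmvnorm_log(Z[, cols_joint, drop = FALSE],
                      J[cols_joint, cols_joint])) +
      mean(dmvnorm_log(Z[, cols_marg, drop = FALSE],
                       J[cols_marg, cols_marg]))
  }
  # H(Y|X) = h(X, Y) - h(X): joint cols 1:4 vs past cols 1:2
  h_cond_whole <- h_pair(1:4, 1:2)
  h_cond_1 <- h_pair(c(1, 3), 1)
  h_cond_2 <- h_pair(c(2, 4), 2)
  expect_equal(si, h_cond_1 + h_cond_2 - h_cond_whole, tolerance = 0.02)
  # block-diagonal dynamics with independent noise: SI is exactly zero
  Ad <- diag(c(.5, .4))
  netd <- structure(list(A = Ad, noise_cov = diag(2)), class = "ar_network")
  expect_equal(stochastic_interaction(ar_lagged_gaussian(netd), part), 0)
})

test_that("phi-star is zero for disconnected parts and matches a beta grid", {
  A <- diag(c(.6, .3))
  net <- structure(list(A = A, noise_cov = diag(2)), class = "ar_network")
  m0 <- ar_lagged_gaussian(net)
  expect_equal(phi_star(m0, list(1, 2))$value, 0, tolerance = 1e-9)
  # coupled 2-node model: compare the internal 1-D optimizer against a
  # dense grid evaluation of the mismatched-decoding curve
  set.seed(43)
  m <- random_lagged_model(2)
  ps <- phi_star(m, list(1, 2))
  dec <- lzphi:::mismatched_decoder(m, list(1, 2))
  curve <- lzphi:::phi_star_curve(m, dec)
  grid <- seq(1e-4, 20, length.out = 40001)
  istar_grid <- max(vapply(grid, curve, numeric(1)))
  expect_equal(ps$mi - ps$value, istar_grid, tolerance = 1e-6)
})

test_that("phi-G vanishes on the no-influence manifold and matches a generic KL minimizer", {
  # block-diagonal regression, correlated innovations: still on the manifold
  A <- diag(c(.5, .4))
  Q <- matrix(c(1, .6, .6, 1), 2)
  net <- structure(list(A = A, noise_cov = Q), class = "ar_network")
  expect_equal(phi_g(ar_lagged_gaussian(net), list(1, 2))$value, 0,
               tolerance = 1e-9)
  # coupled model: independent oracle minimizes the full joint KL over a
  # block-constrained model by Nelder-Mead on an unconstrained
  # parametrization (q(X) free, block regression, free residual cov)
  set.seed(44)
  m <- random_lagged_model(2)
  pg <- phi_g(m, list(1, 2))$value
  Sp <- joint_cov(m)
  kl_to <- function(par) {
    Lx <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2)
    Sqx <- Lx %*% t(Lx)
    Aq <- diag(c(par[4], par[5]))
    Le <- matrix(c(exp(par[6]), par[7], 0, exp(par[8])), 2)
    Sqe <- Le %*% t(Le)
    top <- cbind(Sqx, Sqx %*% t(Aq))
    bot <- cbind(Aq %*% Sqx, Aq %*% Sqx %*% t(Aq) + Sqe)
    Sq <- rbind(top, bot)
    0.5 * (sum(diag(solve(Sq, Sp))) - 4 +
             determinant(Sq)$modulus - determinant(Sp)$modulus)
  }
  init <- c(0, 0, 0, 0.1, 0.1, 0, 0, 0)
  opt <- optim(init, kl_to, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  opt <- optim(opt$par, kl_to, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  expect_equal(pg, as.numeric(opt$value), tolerance = 1e-5)
})

test_that("information measures and bounds hold on random models", {
  set.seed(45)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    m <- random_lagged_model(n)
    part <- random_bipartition(n)
    I <- total_lagged_mi(m)
    ps <- phi_star(m, part)$value
    pg <- phi_g(m, part)$value
    si <- stochastic_interaction(m, part)
    expect_gte(ps, 0); expect_lte(ps, I + 1e-9)
    expect_gte(pg, 0); expect_lte(pg, si + 1e-9)
    expect_gte(multi_information(m), 0)
  }
})

test_that("Gaussian informations agree with Monte-Carlo estimates", {
  set.seed(46)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    m <- random_lagged_model(n)
    J <- joint_cov(m)
    N <- 5e4
    Z <- matrix(rnorm(N * 2 * n), N) %*% chol(J)
    lr <- dmvnorm_log(Z, J) -
      dmvnorm_log(Z[, 1:n, drop = FALSE], J[1:n, 1:n]) -
      dmvnorm_log(Z[, (n + 1):(2 * n), drop = FALSE],
                  J[(n + 1):(2 * n), (n + 1):(2 * n)])
    se <- sd(lr) / sqrt(N)
    expect_lt(abs(total_lagged_mi(m) - mean(lr)), 3 * se + 1e-3)
  }
})

test_that("all measures are invariant under simultaneous channel permutation", {
  set.seed(47)
  m <- random_lagged_model(5)
  perm <- sample(5)
  mp <- lagged_gaussian(cov_x = m$cov_x[perm, perm],
                        cov_xy = m$cov_xy[perm, perm],
                        cov_y = m$cov_y[perm, perm])
  part <- list(c(1, 3), c(2, 4, 5))
  part_p <- lapply(part, function(b) match(b, perm))
  for (meas in c("phi_g", "phi_star", "si", "mii")) {
    expect_equal(phi_measure(m, part, meas),
                 phi_measure(mp, part_p, meas), tolerance = 1e-7)
  }
  expect_equal(multi_information(m), multi_information(mp))
})

test_that("Queyranne MIP search finds planted cuts and is deterministic", {
  set.seed(48)
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- matrix(runif(16, 0.1, 0.3), 4)
  A[5:8, 5:8] <- matrix(runif(16, 0.1, 0.3), 4)
  net <- structure(list(A = A, noise_cov = diag(8)), class = "ar_network")
  m <- ar_lagged_gaussian(net)
  for (meas in c("phi_g", "si")) {
    res <- mip_search(m, meas)
    expect_true(setequal(res$partition[[1]], 1:4) ||
                  setequal(res$partition[[1]], 5:8))
    expect_lt(res$value, 1e-8)
    res2 <- mip_search(m, meas)
    expect_identical(res, res2)
  }
})

test_that("hierarchical complex search recovers a planted core", {
  set.seed(49)
  # 3-node strongly interacting core embedded in independent noise channels
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- matrix(c(.4, .3, .2, .3, .4, .3, .2, .3, .4), 3)
  net <- structure(list(A = A, noise_cov = diag(6)), class = "ar_network")
  m <- ar_lagged_gaussian(net)
  res <- complex_search(m, "phi_g")
  exh <- complex_search(m, "phi_g", method = "exhaustive")
  # the complex lies inside the interacting core and attains the same
  # value as exhaustive subset enumeration (ties in identity permitted)
  expect_true(all(res$subset %in% 1:3))
  expect_true(all(exh$subset %in% 1:3))
  expect_equal(res$value, exh$value, tolerance = 1e-9)
})

test_that("hierarchical complex search equals brute force on small random models", {
  set.seed(50)
  for (i in 1:6) {
    n <- sample(4:6, 1)
    m <- random_lagged_model(n)
    h <- complex_search(m, "phi_g")
    e <- complex_search(m, "phi_g", method = "exhaustive")
    expect_equal(h$value, e$value, tolerance = 1e-8)
    expect_true(setequal(h$subset, e$subset))
  }
})
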