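test_that("MVAR least squares recovers generating coefficients", {
  set.seed(60)
  # white noise: all coefficients near zero
  xw <- matrix(rnorm(3 * 5000), 3)
  fw <- fit_mvar(xw, 2)
  expect_lt(max(abs(unlist(fw$A))), 0.05)
  expect_true(fw$stable)
  # known order-4 model at 1e5 samples: coefficients within 0.02 RMS
  n <- 4
  A_true <- list(diag(0.3, n), matrix(0.1, n, n) - diag(0.1, n),
                 diag(0.15, n), matrix(0, n, n))
  A_true[[4]][1, 2] <- 0.2
  x <- matrix(rnorm(n * 200), n, 200)
  T_len <- 1e5 + 200
  X <- matrix(0, n, T_len)
  X[, 1:4] <- rnorm(4 * n)
  for (t in 5:T_len) {
    X[, t] <- rnorm(n)
    for (k in 1:4) X[, t] <- X[, t] + A_true[[k]] %*% X[, t - k]
  }
  X <- X[, 201:T_len]
  fit <- fit_mvar(X, 4)
  rms <- sqrt(mean((unlist(fit$A) - unlist(A_true))^2))
  expect_lt(rms, 0.02)
  # order selection finds the true order
  sel <- select_mvar_order(X, max_order = 6, criterion = "bic")
  expect_identical(sel$order, 4L)
})

test_that("DTF is row-normalized and respects directionality", {
  set.seed(61)
  net <- sample_ar_network(ar_config())
  X <- simulate_ar(net, 6000)[, 1001:6000]
  fit <- fit_mvar(X, 4)
  g2 <- dtf_spectrum(fit, seq(0, 40, 0.5), 500)
  expect_lt(max(abs(apply(g2, c(1, 3), sum) - 1)), 1e-12)
  # strictly unidirectional 2-node coupling: zero DTF in the acausal
  # direction (exact, from the coefficient structure)
  fit2 <- structure(list(A = list(matrix(c(.5, .4, 0, .3), 2)),
                         resid_cov = diag(2), order = 1L, n = 2L,
                         stable = TRUE, nobs = 100L),
                    class = "mvar_fit")
  g22 <- dtf_spectrum(fit2, c(0, 5, 10), 100)
  expect_true(all(g22[1, 2, ] == 0))      # no influence of node 2 on node 1
  expect_true(all(g22[2, 1, ] > 0))
  # 2-node analytic check at f = 0: H = (I - A)^-1 by hand
  H0 <- solve(diag(2) - fit2$A[[1]])
  P0 <- Mod(H0)^2
  expect_equal(g22[, , 1], P0 / rowSums(P0))
})

test_that("band aggregation is an exact normalized trapezoid", {
  freqs <- seq(0, 40, 0.5)
  nf <- length(freqs)
  # frequency-constant gamma: aggregation returns the same value
  g_const <- array(0.25, c(2, 2, nf))
  attr(g_const, "freqs") <- freqs
  W <- band_adjacency(g_const, c(0, 40))
  expect_equal(W[1, 2], 0.25)
  expect_equal(diag(W), c(0, 0))
  # triangular profile peaking mid-band: area is half the peak
  tri <- pmin(freqs, 40 - freqs) / 20
  g_tri <- array(rep(tri, each = 4), c(2, 2, nf))
  attr(g_tri, "freqs") <- freqs
  expect_equal(band_adjacency(g_tri, c(0, 40))[1, 2], 0.5,
               tolerance = 1e-3)
  # random fits stay within [0, 1]
  set.seed(62)
  for (i in 1:20) {
    x <- matrix(rnorm(3 * 2000), 3)
    g2 <- dtf_spectrum(fit_mvar(x, 2), freqs, 500)
    Wr <- band_adjacency(g2, c(0, 40))
    expect_true(all(Wr >= 0 & Wr <= 1))
  }
})

test_that("mean absolute pairwise correlation has its boundary cases", {
  set.seed(63)
  x <- rnorm(2000)
  expect_equal(mean_abs_correlation(rbind(x, x, x)), 1)
  indep <- matrix(rnorm(4 * 20000), 4)
  expect_lt(mean_abs_correlation(indep), 0.03)
  expect_error(mean_abs_correlation(rbind(x, rep(1, 2000))), "constant")
})

test_that("global efficiency follows hand-computed Dijkstra distances", {
  # complete digraph, all weights 0.5: every distance 0.5, GE = 2
  Wc <- matrix(0.5, 4, 4)
  expect_equal(global_efficiency(Wc), 2)
  # relay beats the direct edge: d(1,3) = 0.1 + 0.1 = 0.2
  W <- matrix(0, 3, 3)
  W[1, 2] <- 0.9; W[2, 3] <- 0.9; W[1, 3] <- 0.1
  # hand Dijkstra: 1/d over ordered pairs =
  # (10 + 5 + 10 + 1 + 1 + 1) / 6
  expect_equal(global_efficiency(W), 28 / 6)
  # w = 1 clamps to distance 1e-9 instead of zero
  W1 <- matrix(0, 2, 2); W1[1, 2] <- 1; W1[2, 1] <- 0.5
  expect_equal(global_efficiency(W1), (1e9 + 2) / 2)
})

test_that("directed-weighted Louvain modularity matches exhaustive search", {
  # two disconnected uniform 4-node complete sub-digraphs: Q = 0.5
  W2 <- matrix(0, 8, 8)
  W2[1:4, 1:4] <- 0.7; W2[5:8, 5:8] <- 0.7; diag(W2) <- 0
  set.seed(64)
  res <- directed_modularity(W2)
  expect_equal(res$Q, 0.5)
  expect_identical(length(unique(res$membership[1:4])), 1L)
  expect_identical(length(unique(res$membership[5:8])), 1L)
  expect_false(res$membership[1] == res$membership[5])
  # uniform complete digraph: no community structure
  Wu <- matrix(1, 6, 6); diag(Wu) <- 0
  expect_lt(abs(directed_modularity(Wu)$Q), 1e-9)
  # 5-node random graphs: Louvain never beats, and here attains, the
  # exhaustive optimum
  set.seed(65)
  for (i in 1:10) {
    Wr <- matrix(runif(25), 5, 5); diag(Wr) <- 0
    ql <- directed_modularity(Wr, restarts = 10)$Q
    qe <- exhaustive_modularity(Wr)$Q
    expect_lte(ql, qe + 1e-12)
    expect_gte(ql, qe - 1e-9)
  }
})

test_that("self-loop modularity follows the strength-inclusive convention", {
  # two 3-node cliques plus heavy self-loops
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 0.5; W[4:6, 4:6] <- 0.5
  diag(W) <- 2
  set.seed(67)
  res <- directed_modularity(W, self_loops = TRUE)
  # hand evaluation: the two cliques remain the optimal communities; with
  # self-loops, m = 2*(6*0.5) + 6*2 = 18, every within-community entry
  # (incl. diagonal) counts, strengths include self-weight
  comm <- c(1, 1, 1, 2, 2, 2)
  m <- sum(W)
  s_out <- rowSums(W); s_in <- colSums(W)
  q_hand <- sum((W - outer(s_out, s_in) / m) *
                  outer(comm, comm, "==")) / m
  expect_equal(res$Q, q_hand)
  # the self-loop Q exceeds the zero-diagonal Q here (diagonal mass is
  # concentrated within communities)
  expect_gt(res$Q, 0)
})

test_that("DTF-estimated topology tracks ground-truth topology", {
  set.seed(66)
  cfg <- ar_config(n_networks = 25)
  ge_t <- ge_e <- mw_t <- mw_e <- numeric(25)
  for (i in 1:25) {
    net <- sample_ar_network(cfg)
    X <- simulate_ar(net, 6000)[, 1001:6000]
    fit <- fit_mvar(X, 4)
    W <- band_adjacency(dtf_spectrum(fit, seq(0, 40, 0.5), 500), c(0, 40))
    truth <- graph_metrics(net$A)
    est <- graph_metrics(W)
    ge_t[i] <- truth["GE"]; ge_e[i] <- est["GE"]
    mw_t[i] <- truth["muW"]; mw_e[i] <- est["muW"]
  }
  expect_gt(spearman(ge_t, ge_e)$rho, 0.5)
  expect_gt(spearman(mw_t, mw_e)$rho, 0.5)
})
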