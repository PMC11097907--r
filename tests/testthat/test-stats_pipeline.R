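test_that("Spearman correlation endpoints and permutation comparison", {
  x <- 1:10
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  # exact permutation p for n <= 7 vs the large-sample approximation:
  # the two must agree in order of magnitude on a strong correlation
  set.seed(90)
  x7 <- rnorm(7); y7 <- x7 + rnorm(7, sd = 0.3)
  obs <- spearman(x7, y7)
  perms <- combinat_perms <- NULL
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rhos <- vapply(all_perm(1:7), function(p)
    cor(rank(x7), rank(y7[p])), numeric(1))
  p_exact <- mean(abs(rhos) >= abs(obs$rho) - 1e-12)
  expect_lt(abs(log10(obs$p) - log10(p_exact)), 1)
})

test_that("Wilcoxon signed-rank statistic and exact enumeration", {
  # 9 pairs, all differences one sign: W = 0, exact two-sided p < .005
  x <- 1:9 + 10
  y <- 1:9
  res <- wilcoxon_signed_rank(x, y)
  expect_identical(res$W, 0)
  expect_lt(res$p, 0.005)
  # antisymmetric differences: p near 1
  d <- c(-4, -3, -2, -1, 1, 2, 3, 4) + 1e-9 * (1:8)
  res2 <- wilcoxon_signed_rank(d, rep(0, 8))
  expect_gt(res2$p, 0.7)
  # n <= 10 exact p equals full sign enumeration of the rank sums
  set.seed(91)
  for (rep_i in 1:5) {
    n <- sample(6:10, 1)
    dd <- round(rnorm(n), 3)
    dd <- dd[dd != 0]
    n <- length(dd)
    res3 <- wilcoxon_signed_rank(dd, rep(0, n))
    r <- rank(abs(dd))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    v_obs <- sum(r[dd > 0])
    w_all <- pmin(v_all, n * (n + 1) / 2 - v_all)
    w_obs <- min(v_obs, n * (n + 1) / 2 - v_obs)
    p_enum <- mean(w_all <= w_obs)
    expect_equal(res3$p, p_enum, tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

make_table <- function(vals_by_cond) {
  do.call(rbind, lapply(names(vals_by_cond), function(cc) {
    v <- vals_by_cond[[cc]]
    do.call(rbind, lapply(seq_len(nrow(v)), function(u)
      measure_rows(paste0("rat", u), cc, v[u, ])))
  }))
}

test_that("relative change has exact arithmetic and label antisymmetry", {
  set.seed(92)
  wake <- cbind(LZs = rep(0.50, 6), ACE = runif(6, 0.8, 0.9))
  anes <- cbind(LZs = rep(0.40, 6), ACE = wake[, "ACE"] * 0.9)
  tab <- make_table(list(wake = wake, anes = anes))
  rc <- relative_change(tab, "wake", "anes")
  expect_equal(rc$change_pct[rc$measure == "LZs"], -20)
  expect_equal(rc$change_pct[rc$measure == "ACE"], -10)
  # identical conditions: 0%
  tab0 <- make_table(list(wake = wake, anes = wake))
  expect_true(all(relative_change(tab0, "wake", "anes")$change_pct == 0))
  # swapping labels flips the sign (magnitudes rescale by the new baseline)
  same_scale <- make_table(list(a = wake, b = wake * 1.1))
  fwd <- relative_change(same_scale, "a", "b")$change_pct
  bwd <- relative_change(same_scale, "b", "a")$change_pct
  expect_equal(fwd, c(10, 10))
  expect_equal(bwd, c(-100 / 11, -100 / 11))
  expect_true(all(sign(fwd) == -sign(bwd)))
})

test_that("condition contrasts are label-symmetric in p-value", {
  set.seed(93)
  wake <- cbind(LZs = runif(8, 0.45, 0.55), PhiG = runif(8, 0.02, 0.04))
  anes <- cbind(LZs = wake[, "LZs"] - runif(8, 0.05, 0.15),
                PhiG = wake[, "PhiG"] + runif(8, 0.01, 0.03))
  tab <- make_table(list(wake = wake, anes = anes))
  c_ab <- condition_contrast(tab, "wake", "anes")
  c_ba <- condition_contrast(tab, "anes", "wake")
  expect_equal(c_ab$p, c_ba$p)
  expect_equal(c_ab$W, c_ba$W)
  expect_identical(c_ab$W, c(0, 0))       # consistent one-signed effects
  expect_true(all(sign(c_ab$change_pct) == -sign(c_ba$change_pct)))
})

test_that("correlation matrices are symmetric, masked, and handle degeneracy", {
  set.seed(94)
  n <- 20
  base <- rnorm(n)
  vals <- cbind(A = base + rnorm(n, sd = .2),
                B = -base + rnorm(n, sd = .2),
                C = rnorm(n))
  tab <- do.call(rbind, lapply(seq_len(n), function(u)
    measure_rows(paste0("u", u), "x", vals[u, ])))
  cm <- measure_correlations(tab)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(diag(cm$masked), c(1, 1, 1), ignore_attr = TRUE)
  expect_lt(cm$rho["A", "B"], -0.7)
  # independent-measure cell is zeroed by the mask far more often than a
  # strongly coupled one; with these effect sizes, deterministically here
  expect_equal(cm$masked["A", "B"], cm$rho["A", "B"])
  # two observations: flagged as undefined
  tab2 <- tab[tab$unit %in% c("u1", "u2"), ]
  expect_warning(cm2 <- measure_correlations(tab2), "fewer than 3")
  expect_true(all(is.na(cm2$rho[upper.tri(cm2$rho)])))
  expect_error(check_ok <- measure_correlations(rbind(tab, tab)),
               "duplicate")
})

test_that("the condition study emits contrasts, correlations, and merges PCI", {
  set.seed(95)
  wake <- cbind(LZs = runif(8, .45, .55), SE = runif(8, -1.5, -1.1))
  anes <- cbind(LZs = wake[, "LZs"] - .1, SE = wake[, "SE"] - 1.5)
  tab <- make_table(list(wake = wake, propofol = anes))
  pci <- data.frame(unit = rep(paste0("rat", 1:8), 2),
                    condition = rep(c("wake", "propofol"), each = 8),
                    value = c(runif(8, 30, 50), runif(8, 4, 10)))
  res <- run_condition_study(tab, baseline = "wake", pci = pci)
  expect_true("PCIst" %in% rownames(res$correlations$rho))
  expect_true(all(c("LZs", "SE") %in% res$contrasts$measure))
  expect_true(all(res$contrasts$p >= 0 & res$contrasts$p <= 1))
  # permuted labels: no more significant contrasts than chance
  set.seed(96)
  perm_tab <- tab
  for (m in unique(perm_tab$measure)) {
    sel <- perm_tab$measure == m
    perm_tab$value[sel] <- sample(perm_tab$value[sel])
  }
  res_perm <- run_condition_study(perm_tab, baseline = "wake")
  expect_lt(mean(res_perm$contrasts$p < 0.05), 0.5)
})
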