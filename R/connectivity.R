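# Directed functional connectivity (MVAR + DTF) and graph topology.

#' Fit a multivariate autoregressive (MVAR) model
#'
#' Ordinary least squares fit of `X[t] = sum_k A_k X[t-k] + e[t]` across all
#' channels jointly.
#'
#' @param x Numeric matrix, channels x samples.
#' @param order Model order `p` (number of lags).
#' @return Object of class `mvar_fit` with `A` (list of p coefficient
#'   matrices), `resid_cov`, `order`, `n`, `stable` (companion-matrix
#'   spectral radius < 1), and `nobs`.
#' @export
fit_mvar <- function(x, order = 4) {
  stopifnot(is.matrix(x), order >= 1)
  n <- nrow(x); T <- ncol(x)
  if (T - order < 10 * n * order)
    stop("need at least 10 * channels * order effective samples")
  Y <- t(x[, (order + 1):T, drop = FALSE])          # (T-p) x n
  Z <- do.call(cbind, lapply(seq_len(order), function(k)
    t(x[, (order + 1 - k):(T - k), drop = FALSE]))) # (T-p) x (n*p)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) stop("ill-conditioned design matrix")
  B <- qr.coef(qrz, Y)                              # (n*p) x n
  E <- Y - Z %*% B
  A <- lapply(seq_len(order), function(k)
    t(B[((k - 1) * n + 1):(k * n), , drop = FALSE]))
  comp <- matrix(0, n * order, n * order)
  for (k in seq_len(order)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- A[[k]]
  if (order > 1)
    comp[(n + 1):(n * order), 1:(n * (order - 1))] <- diag(n * (order - 1))
  structure(list(A = A, resid_cov = crossprod(E) / (nrow(E) - ncol(Z)),
                 order = order, n = n,
                 stable = spectral_radius(comp) < 1, nobs = nrow(Y)),
            class = "mvar_fit")
}

#' MVAR order selection by information criterion
#'
#' Fits models of order `1..max_order` and returns the order minimizing the
#' chosen criterion based on the log determinant of the residual
#' covariance.
#'
#' @param x Channels x samples matrix.
#' @param max_order Largest order to try.
#' @param criterion `"aic"` or `"bic"`.
#' @return List with `order` and `scores`.
#' @export
select_mvar_order <- function(x, max_order = 8, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  n <- nrow(x)
  scores <- vapply(seq_len(max_order), function(p) {
    fit <- fit_mvar(x, p)
    T_eff <- fit$nobs
    ld <- as.numeric(determinant(fit$resid_cov, logarithm = TRUE)$modulus)
    pen <- if (criterion == "aic") 2 else log(T_eff)
    ld + pen * p * n^2 / T_eff
  }, numeric(1))
  list(order = which.min(scores), scores = scores)
}

#' Directed transfer function spectrum
#'
#' Computes the normalized DTF
#' `gamma2_ij(f) = |H_ij(f)|^2 / sum_m |H_im(f)|^2` with
#' `H(f) = (I - sum_k A_k exp(-i 2 pi f k / rate))^-1`. Every row of
#' `gamma2` sums to one at every frequency.
#'
#' @param fit An `mvar_fit`.
#' @param freqs Frequencies in Hz at which to evaluate.
#' @param rate Sampling rate in Hz.
#' @return Array n x n x length(freqs) of normalized squared DTF values,
#'   with attribute `freqs`.
#' @export
dtf_spectrum <- function(fit, freqs, rate) {
  stopifnot(inherits(fit, "mvar_fit"), length(freqs) >= 1, rate > 0)
  n <- fit$n
  gamma2 <- array(NA_real_, c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(n) + 0i
    for (k in seq_len(fit$order))
      Af <- Af - fit$A[[k]] * exp(-2i * pi * freqs[fi] * k / rate)
    H <- tryCatch(solve(Af), error = function(e)
      stop("singular transfer matrix at ", freqs[fi], " Hz"))
    P <- Mod(H)^2
    gamma2[, , fi] <- P / rowSums(P)
  }
  attr(gamma2, "freqs") <- freqs
  gamma2
}

#' Band-aggregated DTF adjacency
#'
#' Averages the DTF over a frequency band by the trapezoidal area under the
#' curve divided by the band width, keeping weights in `[0, 1]`; the
#' diagonal is zeroed for graph use unless `keep_diag` is set (self-inflow
#' retained, as when modularity is computed with self-loops).
#'
#' @param gamma2 Output of [dtf_spectrum()].
#' @param band Length-2 numeric, band limits in Hz.
#' @param keep_diag Retain the diagonal (self-influence) entries.
#' @return n x n weight matrix (class `matrix`).
#' @export
band_adjacency <- function(gamma2, band = c(0, 40), keep_diag = FALSE) {
  freqs <- attr(gamma2, "freqs")
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) < 2) stop("band must contain at least two frequencies")
  f <- freqs[sel]
  wts <- diff(f)
  n <- dim(gamma2)[1]
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    y <- gamma2[i, j, sel]
    W[i, j] <- sum((y[-length(y)] + y[-1]) / 2 * wts) / (max(f) - min(f))
  }
  if (!keep_diag) diag(W) <- 0
  W
}

#' Mean absolute pairwise correlation ("mean coherence")
#'
#' Mean over unordered channel pairs of the absolute zero-lag Pearson
#' correlation; for epoched input, computed per epoch and averaged.
#'
#' @param x Channels x samples matrix, or an `eeg_epochs` object.
#' @return Scalar in `[0, 1]`.
#' @export
mean_abs_correlation <- function(x) {
  one <- function(m) {
    if (any(apply(m, 1, sd) == 0)) stop("constant channel")
    cc <- cor(t(m))
    mean(abs(cc[upper.tri(cc)]))
  }
  if (inherits(x, "eeg_epochs"))
    return(mean(vapply(seq_len(dim(x$data)[3]), function(e)
      one(x$data[, , e]), numeric(1))))
  stopifnot(is.matrix(x), nrow(x) >= 2)
  one(x)
}

#' Global efficiency of a weighted digraph
#'
#' Edge distances are the complement of the edge weights (`d = 1 - w`, so
#' high weight means short distance; absent edges, `w = 0`, get distance
#' one). All-pairs shortest paths are computed with Dijkstra's algorithm and
#' the global efficiency is the mean over ordered pairs of inverse shortest
#' distance. A weight of exactly one is clamped to distance 1e-9.
#'
#' @param W n x n nonnegative weight matrix in `[0, 1]`; diagonal ignored.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), nrow(W) >= 2,
            all(W >= 0), all(W <= 1))
  n <- nrow(W)
  D <- 1 - W
  D[D <= 0] <- 1e-9
  diag(D) <- 0
  g <- igraph::graph_from_adjacency_matrix(D, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  sp <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  mean(1 / sp[row(sp) != col(sp)])
}

#' Mean connection strength
#'
#' Mean of the off-diagonal weights of an adjacency matrix.
#' @param W Square weight matrix.
#' @return Scalar.
#' @export
mean_connection_strength <- function(W) {
  mean(W[row(W) != col(W)])
}

directed_modularity_value <- function(W, comm) {
  m <- sum(W)
  if (m <= 0) stop("empty graph")
  s_out <- rowSums(W); s_in <- colSums(W)
  same <- outer(comm, comm, "==")
  sum((W - outer(s_out, s_in) / m) * same) / m
}

#' Directed-weighted modularity with Louvain optimization
#'
#' Modularity for weighted directed networks,
#' `Q = (1/m) * sum_ij (w_ij - s_i^out s_j^in / m) * [c_i == c_j]`,
#' optimized with the Louvain two-phase heuristic (local node moves
#' followed by community aggregation), best of `restarts` randomized runs.
#'
#' @param W n x n nonnegative weight matrix; the diagonal is zeroed unless
#'   `self_loops = TRUE`, in which case self-connections contribute to the
#'   strengths and total weight (the convention of the common
#'   brain-connectivity implementations).
#' @param restarts Number of randomized restarts.
#' @param self_loops Retain diagonal entries as self-loops.
#' @return List with `Q` and `membership` (integer community labels).
#' @export
directed_modularity <- function(W, restarts = 10, self_loops = FALSE) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
  if (!self_loops) diag(W) <- 0
  if (sum(W) <= 0) stop("empty graph")
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- louvain_dir_once(W)
    if (is.null(best) || res$Q > best$Q) best <- res
  }
  best
}

louvain_dir_once <- function(W0) {
  res <- louvain_dir_core(W0)
  res$Q <- directed_modularity_value(W0, res$membership)
  res
}

louvain_dir_core <- function(W) {
  n0 <- nrow(W)
  node_map <- seq_len(n0)            # original node -> current super-node
  repeat {
    n <- nrow(W)
    m <- sum(W)
    comm <- seq_len(n)
    k_out <- rowSums(W); k_in <- colSums(W)
    sig_out <- k_out; sig_in <- k_in  # per community totals
    improved_any <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(n)) {
        ci <- comm[i]
        # weights from/to node i per community
        w_i_to <- tapply(W[i, ], comm, sum)
        w_i_from <- tapply(W[, i], comm, sum)
        link <- function(cc) {
          a <- w_i_to[as.character(cc)]; b <- w_i_from[as.character(cc)]
          (if (is.na(a)) 0 else a) + (if (is.na(b)) 0 else b)
        }
        # remove i from its community
        sig_out[ci] <- sig_out[ci] - k_out[i]
        sig_in[ci] <- sig_in[ci] - k_in[i]
        base_link <- link(ci) - 2 * W[i, i]
        cand <- unique(c(ci, comm[W[i, ] > 0 | W[, i] > 0]))
        gains <- vapply(cand, function(cc) {
          l <- if (cc == ci) base_link else link(cc)
          l / m - (k_out[i] * sig_in[cc] + k_in[i] * sig_out[cc]) / m^2
        }, numeric(1))
        target <- cand[which.max(gains)]
        if (gains[match(target, cand)] <=
            gains[match(ci, cand)] + 1e-12) target <- ci
        comm[i] <- target
        sig_out[target] <- sig_out[target] + k_out[i]
        sig_in[target] <- sig_in[target] + k_in[i]
        if (target != ci) { improved <- TRUE; improved_any <- TRUE }
      }
      if (!improved) break
    }
    comm <- match(comm, unique(comm))
    node_map <- comm[node_map]
    if (!improved_any || max(comm) == n) break
    # aggregate communities into super-nodes
    nc <- max(comm)
    Wn <- matrix(0, nc, nc)
    for (a in seq_len(nc)) for (b in seq_len(nc))
      Wn[a, b] <- sum(W[comm == a, comm == b, drop = FALSE])
    if (nc == nrow(W)) break
    W <- Wn
  }
  # Q is recomputed on the original graph by the caller so the exhaustive
  # oracle and Louvain share one modularity definition
  list(Q = NA_real_, membership = node_map)
}

#' Exhaustive maximum directed modularity (oracle for small graphs)
#'
#' Enumerates all set partitions of the nodes and returns the maximum
#' directed-weighted modularity. Intended for n <= 8.
#'
#' @param W Square weight matrix; diagonal zeroed.
#' @param max_communities Optional cap on the number of communities.
#' @return List with `Q` and `membership`.
#' @export
exhaustive_modularity <- function(W, max_communities = Inf) {
  diag(W) <- 0
  n <- nrow(W)
  stopifnot(n <= 10)
  best <- list(Q = -Inf, membership = rep(1L, n))
  gen <- function(i, comm, k) {
    if (i > n) {
      if (k <= max_communities) {
        q <- directed_modularity_value(W, comm[seq_len(n)])
        if (q > best$Q) best <<- list(Q = q, membership = comm[seq_len(n)])
      }
      return(invisible(NULL))
    }
    for (cc in seq_len(min(k + 1, n))) {
      comm[i] <- cc
      gen(i + 1, comm, max(k, cc))
    }
  }
  gen(1L, integer(n), 0L)
  best
}
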