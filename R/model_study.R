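# Drivers: per-network measures for the autoregressive simulation study and
# the per-recording spontaneous-EEG measure battery.

#' Graph-topology summary of a weight matrix
#'
#' Global efficiency, directed-weighted Louvain modularity, and mean
#' connection strength of a nonnegative weight matrix. Efficiency and mean
#' strength always ignore the diagonal (weights clipped to `[0, 1]` for
#' the distance transform); modularity either zeroes the diagonal or, with
#' `modularity_self_loops = TRUE`, keeps self-connections as self-loops.
#'
#' @param W Square nonnegative weight matrix.
#' @param restarts Louvain restarts.
#' @param modularity_self_loops Keep the diagonal for the modularity term.
#' @return Named numeric vector `GE`, `Q`, `muW`.
#' @export
graph_metrics <- function(W, restarts = 10,
                          modularity_self_loops = FALSE) {
  Wz <- W
  diag(Wz) <- 0
  Wc <- pmin(pmax(Wz, 0), 1)
  Wq <- if (modularity_self_loops) pmax(W, 0) else Wc
  c(GE = global_efficiency(Wc),
    Q = directed_modularity(Wq, restarts = restarts,
                            self_loops = modularity_self_loops)$Q,
    muW = mean_connection_strength(Wc))
}

#' Spontaneous measures of one simulated network
#'
#' Simulates the network, discards the burn-in, and computes the full
#' measure battery: LZs and ACE on 4 s-equivalent segments, the
#' Gaussian-model information measures (MI, MII, SI, phi-star, phi-G; the
#' partitioned measures at their Queyranne MIPs) on the pooled series,
#' mean absolute pairwise correlation, and DTF-estimated graph topology,
#' together with ground-truth topology on the weight matrix itself. Modularity keeps
#' self-connections as self-loops on both the estimated and the true
#' matrices; efficiency and mean strength ignore the diagonal.
#'
#' @param net An `ar_network`.
#' @param steps Simulation steps.
#' @param burn_in Fraction of initial steps discarded.
#' @param rate Nominal sampling rate in Hz assigned to the model steps
#'   (the series is treated like EEG sampled at this rate).
#' @param segment_len Samples per segment for the diversity measures.
#' @param tau Lag for the Gaussian model.
#' @param mvar_order MVAR order for the DTF.
#' @param band DTF aggregation band in Hz.
#' @param k_shuffle Surrogate shuffles for LZ/ACE normalization.
#' @return Named numeric vector of measures.
#' @export
network_measures <- function(net, steps = 10000, burn_in = 0.1, rate = 500,
                             segment_len = 2000, tau = 1, mvar_order = 4,
                             band = c(0, 40), k_shuffle = 10) {
  X <- simulate_ar(net, steps)
  X <- X[, (floor(steps * burn_in) + 1):steps, drop = FALSE]
  n <- nrow(X)

  # diversity on non-overlapping segments, averaged
  n_seg <- floor(ncol(X) / segment_len)
  segs <- lapply(seq_len(n_seg), function(s)
    X[, ((s - 1) * segment_len + 1):(s * segment_len)])
  lz_val <- mean(vapply(segs, lzs, numeric(1), k = k_shuffle))
  ace_val <- mean(vapply(segs, ace, numeric(1), k = k_shuffle))

  model <- fit_lagged_gaussian(X, tau = tau)
  mi_val <- multi_information(model)
  mii_val <- mip_search(model, "mii")$value
  si_val <- mip_search(model, "si")$value
  ps_val <- mip_search(model, "phi_star")$value
  pg_val <- mip_search(model, "phi_g")$value

  coh <- mean_abs_correlation(X)

  freqs <- seq(band[1], band[2], by = 0.5)
  fit <- fit_mvar(X, order = mvar_order)
  W_est <- band_adjacency(dtf_spectrum(fit, freqs, rate), band,
                          keep_diag = TRUE)
  est <- graph_metrics(W_est, modularity_self_loops = TRUE)
  truth <- graph_metrics(net$A, modularity_self_loops = TRUE)

  c(LZs = lz_val, ACE = ace_val, MI = mi_val, MII = mii_val, SI = si_val,
    PhiStar = ps_val, PhiG = pg_val, C = coh,
    GE = unname(est["GE"]), Q = unname(est["Q"]), muW = unname(est["muW"]),
    c_true = net$noise_corr, GE_true = unname(truth["GE"]),
    Q_true = unname(truth["Q"]), muW_true = unname(truth["muW"]))
}

#' Run the autoregressive model study
#'
#' Samples `config$n_networks` networks, simulates each for `config$steps`
#' steps, computes the full measure battery per network, and returns the
#' long measure table together with the cross-network Spearman correlation
#' matrix (non-significant cells zeroed in `$correlations$masked`).
#' Networks whose measure computation fails are dropped and recorded.
#'
#' @param config An [ar_config()].
#' @param seed Integer seed for the whole study.
#' @param alpha Significance threshold for the correlation mask.
#' @param ... Passed to [network_measures()].
#' @return List with `table` (long format), `wide` (networks x measures),
#'   `correlations`, and `failed` (ids of dropped networks).
#' @export
run_model_study <- function(config, seed = 1, alpha = 0.05, ...) {
  stopifnot(inherits(config, "ar_config"))
  set.seed(seed)
  rows <- vector("list", config$n_networks)
  failed <- integer(0)
  for (i in seq_len(config$n_networks)) {
    net <- sample_ar_network(config)
    vals <- tryCatch(network_measures(net, steps = config$steps, ...),
                     error = function(e) e)
    if (inherits(vals, "error")) {
      failed <- c(failed, i)
      next
    }
    rows[[i]] <- measure_rows(sprintf("net%04d", i), "model", vals,
                              provenance = sprintf("seed=%d", seed))
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  wide <- NULL
  correlations <- NULL
  if (!is.null(table)) {
    wide <- do.call(rbind, lapply(split(table, table$unit), function(d)
      setNames(d$value, d$measure)))
    n_ok <- nrow(wide)
    if (n_ok >= 3) {
      correlations <- measure_correlations(table, alpha = alpha)
    } else {
      warning("fewer than 3 networks succeeded; correlations undefined")
    }
  }
  list(table = table, wide = wide, correlations = correlations,
       failed = failed)
}

#' Spontaneous measure battery for one epoched recording
#'
#' The per-epoch averaging convention: diversity and spectral measures are
#' computed per epoch and averaged; the Gaussian information measures are
#' computed per epoch (or on the pooled covariance when `pooled = TRUE`)
#' and averaged, with the partitioned measures at their Queyranne MIPs.
#'
#' @param epochs An `eeg_epochs` object.
#' @param tau Lag in samples for the Gaussian model.
#' @param pooled Pool epochs into one covariance fit instead of averaging
#'   per-epoch measures.
#' @param se_band Band for the spectral exponent, Hz.
#' @param mvar_order,dtf_band DTF settings.
#' @param k_shuffle Surrogate shuffles for the diversity measures.
#' @param include_sce Compute SCE (the slowest diversity measure).
#' @return Named numeric vector of measures.
#' @export
spontaneous_measures <- function(epochs, tau = 1, pooled = FALSE,
                                 se_band = c(20, 40), mvar_order = 4,
                                 dtf_band = c(0, 40), k_shuffle = 10,
                                 include_sce = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  ep_list <- as_epoch_list(epochs)

  lz_val <- lzs(epochs, k = k_shuffle)
  ace_val <- ace(epochs, k = k_shuffle)
  sce_val <- if (include_sce) sce(epochs, k = k_shuffle) else NA_real_
  se_val <- spectral_exponent(welch_psd(epochs), band = se_band)
  coh <- mean_abs_correlation(epochs)

  phi_of_model <- function(model) {
    c(MI = multi_information(model),
      MII = mip_search(model, "mii")$value,
      SI = mip_search(model, "si")$value,
      PhiStar = mip_search(model, "phi_star")$value,
      PhiG = mip_search(model, "phi_g")$value)
  }
  if (pooled) {
    pooled_x <- matrix(epochs$data, d[1], d[2] * d[3])
    phis <- phi_of_model(fit_lagged_gaussian(pooled_x, tau = tau))
  } else {
    phis <- rowMeans(vapply(ep_list, function(ep)
      phi_of_model(fit_lagged_gaussian(ep, tau = tau)), numeric(5)))
  }

  freqs <- seq(dtf_band[1], dtf_band[2], by = 0.5)
  W_acc <- 0
  for (ep in ep_list) {
    fit <- fit_mvar(ep, order = mvar_order)
    W_acc <- W_acc + band_adjacency(dtf_spectrum(fit, freqs, epochs$rate),
                                    dtf_band)
  }
  gm <- graph_metrics(W_acc / length(ep_list))

  c(LZs = lz_val, ACE = ace_val, SCE = sce_val, SE = se_val, phis,
    C = coh, GE = unname(gm["GE"]), Q = unname(gm["Q"]),
    muW = unname(gm["muW"]))
}
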