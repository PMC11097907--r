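# Signal-diversity and spectral measures.

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal (Hilbert transform in the imaginary
#' part) of a real vector.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Binarize an epoch by Hilbert amplitude
#'
#' Per channel, the instantaneous amplitude (modulus of the analytic
#' signal) is thresholded at its own epoch mean; samples above the mean
#' map to one. Constant channels produce an all-zero row and are flagged in
#' the `constant_channels` attribute.
#'
#' @param epoch Channels x samples numeric matrix.
#' @return Binary matrix of the same shape with attribute
#'   `constant_channels` (integer indices).
#' @export
binarize_hilbert <- function(epoch) {
  stopifnot(is.matrix(epoch), ncol(epoch) >= 2)
  const <- integer(0)
  bits <- matrix(0L, nrow(epoch), ncol(epoch))
  for (i in seq_len(nrow(epoch))) {
    if (sd(epoch[i, ]) == 0) {
      const <- c(const, i)
      next
    }
    env <- Mod(analytic_signal(epoch[i, ]))
    bits[i, ] <- as.integer(env > mean(env))
  }
  attr(bits, "constant_channels") <- const
  bits
}

#' LZ76 parse count of a binary sequence
#'
#' Number of phrases in the Lempel-Ziv 1976 exhaustive-history parse.
#'
#' @param bits Integer/logical vector of 0s and 1s.
#' @return Integer parse count.
#' @export
lz76 <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0) stop("empty sequence")
  if (!all(bits %in% c(0L, 1L))) stop("sequence must be binary")
  .lz76_count_cpp(bits)
}

#' Normalized LZ76 complexity
#'
#' Default normalization divides the parse count by the mean parse count of
#' `k` within-sequence shuffles of the same bits, giving values in roughly
#' `[0, 1]` with one meaning "as complex as its shuffled surrogate". The
#' classical asymptotic normalization `c * log2(n) / n` is available via
#' `method = "asymptotic"`.
#'
#' @param bits Binary vector.
#' @param method `"shuffle"` or `"asymptotic"`.
#' @param k Number of shuffles for the surrogate normalization.
#' @return Scalar normalized complexity.
#' @export
lz76_normalized <- function(bits, method = c("shuffle", "asymptotic"),
                            k = 10) {
  method <- match.arg(method)
  bits <- as.integer(bits)
  c_raw <- lz76(bits)
  if (method == "asymptotic") {
    return(c_raw * log2(length(bits)) / length(bits))
  }
  c_sh <- mean(vapply(seq_len(k), function(i)
    .lz76_count_cpp(sample(bits)), numeric(1)))
  if (c_sh == 0) return(0)
  c_raw / c_sh
}

as_epoch_list <- function(x) {
  if (inherits(x, "eeg_epochs"))
    return(lapply(seq_len(dim(x$data)[3]), function(e) x$data[, , e]))
  if (is.matrix(x)) return(list(x))
  stop("expected an eeg_epochs object or a channels x samples matrix")
}

#' Mean single-channel Lempel-Ziv complexity (LZs)
#'
#' Per epoch and channel, the channel is Hilbert-binarized and its
#' normalized LZ76 complexity computed; values are averaged over channels
#' and then over epochs. Epochs in which every channel is constant are
#' excluded with a warning.
#'
#' @param x An `eeg_epochs` object or a channels x samples matrix (treated
#'   as a single epoch).
#' @param method,k Passed to [lz76_normalized()].
#' @return Scalar LZs value.
#' @export
lzs <- function(x, method = "shuffle", k = 10) {
  epochs <- as_epoch_list(x)
  vals <- vapply(epochs, function(ep) {
    bits <- binarize_hilbert(ep)
    keep <- setdiff(seq_len(nrow(bits)), attr(bits, "constant_channels"))
    if (length(keep) == 0) return(NA_real_)
    mean(vapply(keep, function(i)
      lz76_normalized(bits[i, ], method = method, k = k), numeric(1)))
  }, numeric(1))
  if (anyNA(vals)) {
    warning("excluded ", sum(is.na(vals)), " all-constant epoch(s)")
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Shannon entropy of a coalition sequence
#'
#' Entropy (bits) of the empirical distribution of binary column patterns
#' ("coalitions") of a channels x samples binary matrix.
#'
#' @param bits Binary matrix, channels x samples.
#' @return Entropy in bits.
#' @export
coalition_entropy <- function(bits) {
  pat <- apply(bits, 2, paste, collapse = "")
  p <- table(pat) / length(pat)
  -sum(p * log2(p))
}

shuffle_rows <- function(bits) {
  t(apply(bits, 1, sample))
}

#' Amplitude coalition entropy (ACE)
#'
#' Entropy over time of the set of channels whose Hilbert amplitude is
#' above its epoch mean, normalized by the same entropy after independent
#' within-channel time shuffling (mean of `k` shuffles). Computed per epoch
#' and averaged.
#'
#' @param x An `eeg_epochs` object or channels x samples matrix.
#' @param k Number of normalization shuffles.
#' @return Scalar in approximately `[0, 1]`.
#' @export
ace <- function(x, k = 10) {
  epochs <- as_epoch_list(x)
  stopifnot(nrow(epochs[[1]]) >= 2)
  mean(vapply(epochs, function(ep) {
    bits <- binarize_hilbert(ep)
    h <- coalition_entropy(bits)
    if (h == 0) return(0)
    h_sh <- mean(vapply(seq_len(k), function(i)
      coalition_entropy(shuffle_rows(bits)), numeric(1)))
    if (h_sh == 0) return(0)
    h / h_sh
  }, numeric(1)))
}

phase_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, 2 * pi - d, d)
}

sce_epoch <- function(phases, threshold, k) {
  n <- nrow(phases)
  per_channel <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    coal <- vapply(others, function(j)
      as.integer(phase_diff(phases[i, ], phases[j, ]) < threshold),
      integer(ncol(phases)))
    bits <- t(coal)                       # (n-1) x samples
    h <- coalition_entropy(bits)
    h_sh <- mean(vapply(seq_len(k), function(s)
      coalition_entropy(shuffle_rows(bits)), numeric(1)))
    if (h_sh == 0) return(0)
    h / h_sh
  }, numeric(1))
  mean(per_channel)
}

#' Synchrony coalition entropy (SCE)
#'
#' For each channel, the coalition at each sample is the set of other
#' channels whose instantaneous phase (Hilbert) lies within `threshold`
#' radians of it; the entropy of that coalition sequence is normalized by a
#' within-channel time-shuffled surrogate (mean of `k` shuffles) and
#' averaged over channels, then over epochs.
#'
#' @param x An `eeg_epochs` object or channels x samples matrix.
#' @param threshold Synchrony threshold in radians.
#' @param k Number of surrogate shuffles.
#' @return Scalar in approximately `[0, 1]`.
#' @export
sce <- function(x, threshold = 0.8, k = 10) {
  epochs <- as_epoch_list(x)
  stopifnot(nrow(epochs[[1]]) >= 2)
  mean(vapply(epochs, function(ep) {
    phases <- t(apply(ep, 1, function(ch) Arg(analytic_signal(ch))))
    sce_epoch(phases, threshold, k)
  }, numeric(1)))
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram per channel. For epoched input the
#' spectra are additionally averaged across epochs.
#'
#' @param x An `eeg_epochs` object or channels x samples matrix.
#' @param rate Sampling rate in Hz (taken from the object if epoched).
#' @param window Segment length in seconds.
#' @param overlap Segment overlap fraction in `[0, 1)`.
#' @return Object of class `spectrum_set`: list with `freqs` (Hz) and
#'   `power` (channels x frequencies, units^2 / Hz).
#' @export
welch_psd <- function(x, rate = NULL, window = 1, overlap = 0.5) {
  if (inherits(x, "eeg_epochs")) {
    rate <- x$rate
    epochs <- as_epoch_list(x)
  } else {
    stopifnot(is.matrix(x), !is.null(rate))
    epochs <- list(x)
  }
  L <- round(window * rate)
  stopifnot(L >= 4, L <= ncol(epochs[[1]]))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
  step <- max(1, round(L * (1 - overlap)))
  nf <- floor(L / 2) + 1
  freqs <- (seq_len(nf) - 1) * rate / L
  scale <- rate * sum(w^2)
  pows <- lapply(epochs, function(ep) {
    starts <- seq(1, ncol(ep) - L + 1, by = step)
    P <- matrix(0, nrow(ep), nf)
    for (i in seq_len(nrow(ep))) {
      acc <- numeric(nf)
      for (s in starts) {
        seg <- ep[i, s:(s + L - 1)]
        seg <- (seg - mean(seg)) * w
        sp <- Mod(fft(seg)[seq_len(nf)])^2 / scale
        # one-sided: double everything except DC (and Nyquist when L even)
        dbl <- rep(2, nf); dbl[1] <- 1
        if (L %% 2 == 0) dbl[nf] <- 1
        acc <- acc + sp * dbl
      }
      P[i, ] <- acc / length(starts)
    }
    P
  })
  power <- Reduce(`+`, pows) / length(pows)
  structure(list(freqs = freqs, power = power), class = "spectrum_set")
}

#' Spectral exponent (log-log PSD slope) in a band
#'
#' Ordinary least squares slope of `log10(power)` against
#' `log10(frequency)` restricted to `band`, computed per channel and
#' averaged.
#'
#' @param spec A `spectrum_set` from [welch_psd()].
#' @param band Length-2 numeric band limits in Hz.
#' @return Scalar slope (dimensionless).
#' @export
spectral_exponent <- function(spec, band = c(20, 40)) {
  stopifnot(inherits(spec, "spectrum_set"))
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2] &
                 spec$freqs > 0)
  if (length(sel) < 3) stop("need at least 3 frequency bins in band")
  lf <- log10(spec$freqs[sel])
  slopes <- apply(spec$power[, sel, drop = FALSE], 1, function(p) {
    if (any(p <= 0)) stop("zero power bin inside band")
    unname(coef(lm(log10(p) ~ lf))[2])
  })
  mean(slopes)
}
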