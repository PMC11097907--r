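# Synthetic rat-like EEG generator.
#
# Spectrally shaped Gaussian noise (1/f^gamma), optionally mixed across
# channels, with a shared broadband driver and a slow (< 4 Hz) bistable
# admixture that both adds a rhythm and gates the broadband amplitude.
# This is a statistical emulator exposing the knobs the measures respond
# to, not a biophysical model.

#' Synthetic EEG generation profile
#'
#' @param n_channels Number of channels.
#' @param rate Sampling rate in Hz.
#' @param n_epochs Number of epochs.
#' @param epoch_len Epoch length in seconds (sample count must be
#'   integral).
#' @param spectral_gamma Exponent of the 1/f^gamma background (wake-like
#'   around 1.3, deep-anesthesia-like around 3).
#' @param slow_osc_fraction Fraction in `[0, 1]` of slow-wave admixture.
#' @param common_driver_gain Nonnegative gain of a shared broadband
#'   source; raises between-channel zero-lag correlation monotonically.
#' @param mixing Optional n x n channel mixing matrix (default identity).
#' @param seed Integer seed; `NA` leaves the RNG state alone.
#' @param condition Condition tag attached to the generated epochs.
#' @return Object of class `eeg_profile`.
#' @export
eeg_profile <- function(n_channels = 16, rate = 500, n_epochs = 80,
                        epoch_len = 4, spectral_gamma = 1.3,
                        slow_osc_fraction = 0.05, common_driver_gain = 0.6,
                        mixing = NULL, seed = NA_integer_,
                        condition = "synthetic") {
  stopifnot(n_channels >= 2, rate > 0, n_epochs >= 1,
            abs(epoch_len * rate - round(epoch_len * rate)) < 1e-9,
            spectral_gamma >= 0, slow_osc_fraction >= 0,
            slow_osc_fraction <= 1, common_driver_gain >= 0)
  if (is.null(mixing)) mixing <- diag(n_channels)
  stopifnot(all(dim(mixing) == n_channels))
  structure(list(n_channels = n_channels, rate = rate, n_epochs = n_epochs,
                 epoch_len = epoch_len, spectral_gamma = spectral_gamma,
                 slow_osc_fraction = slow_osc_fraction,
                 common_driver_gain = common_driver_gain, mixing = mixing,
                 seed = seed, condition = condition),
            class = "eeg_profile")
}

#' Condition-specific generation profiles
#'
#' Presets emulating the direction of the main anesthesia effects: wake has
#' a shallow spectral slope and little slow-wave content; propofol-like and
#' sevoflurane-like profiles have steep slopes and strong slow-wave gating;
#' the ketamine-like profile is close to wake.
#'
#' @param condition One of "wake", "propofol", "sevoflurane", "ketamine".
#' @param ... Overrides passed to [eeg_profile()].
#' @return An `eeg_profile`.
#' @export
condition_profile <- function(condition = c("wake", "propofol",
                                            "sevoflurane", "ketamine"),
                              ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    wake = list(spectral_gamma = 1.3, slow_osc_fraction = 0.05,
                common_driver_gain = 0.6),
    propofol = list(spectral_gamma = 3.0, slow_osc_fraction = 0.5,
                    common_driver_gain = 0.9),
    sevoflurane = list(spectral_gamma = 2.8, slow_osc_fraction = 0.45,
                       common_driver_gain = 0.9),
    ketamine = list(spectral_gamma = 1.1, slow_osc_fraction = 0.1,
                    common_driver_gain = 0.6))
  args <- utils::modifyList(c(base, list(condition = condition)), list(...))
  do.call(eeg_profile, args)
}

shaped_noise <- function(L, rate, gamma) {
  z <- rnorm(L)
  if (gamma == 0) return(z)
  f <- (seq_len(L) - 1) * rate / L
  f_fold <- pmin(f, rate - f)             # magnitude response must be even
  w <- pmax(f_fold, 1)^(-gamma / 2)
  w[1] <- 0                               # zero DC
  x <- Re(fft(fft(z) * w, inverse = TRUE) / L)
  x / sd(x)
}

#' Generate a synthetic epoched recording
#'
#' Each epoch is generated independently: per-channel 1/f^gamma shaped
#' noise, a shared broadband driver blended in with
#' `x = (b + g d) / sqrt(1 + g^2)`, a shared slow oscillation (random
#' frequency in 0.8-2 Hz) that gates the broadband amplitude and adds a
#' rhythmic component scaled by `slow_osc_fraction`, and finally the
#' mixing matrix.
#'
#' @param profile An [eeg_profile()].
#' @return An `eeg_epochs` object (values in arbitrary microvolt-like
#'   units).
#' @export
generate_recording <- function(profile) {
  stopifnot(inherits(profile, "eeg_profile"))
  if (!is.na(profile$seed)) set.seed(profile$seed)
  nch <- profile$n_channels
  L <- round(profile$epoch_len * profile$rate)
  g <- profile$common_driver_gain
  s <- profile$slow_osc_fraction
  arr <- array(NA_real_, c(nch, L, profile$n_epochs))
  tt <- (seq_len(L) - 1) / profile$rate
  for (e in seq_len(profile$n_epochs)) {
    d <- shaped_noise(L, profile$rate, profile$spectral_gamma)
    X <- t(vapply(seq_len(nch), function(i) {
      b <- shaped_noise(L, profile$rate, profile$spectral_gamma)
      (b + g * d) / sqrt(1 + g^2)
    }, numeric(L)))
    if (s > 0) {
      f0 <- runif(1, 0.8, 2)
      o <- sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
      gate <- 1 - 0.5 * s * (1 + o)
      X <- sweep(X, 2, gate, `*`) + s * outer(rep(1, nch), o)
    }
    arr[, , e] <- 50 * (profile$mixing %*% X)
  }
  eeg_epochs(arr, profile$rate, condition = profile$condition)
}

#' Write a synthetic fixture to disk
#'
#' Concatenates the epochs into a continuous recording, writes it as EDF
#' and as delimited text, and records the generation profile and seed in a
#' JSON manifest.
#'
#' @param profile An `eeg_profile`.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Invisibly, the manifest path.
#' @export
write_synthetic_fixture <- function(profile, dir, name = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eps <- generate_recording(profile)
  d <- dim(eps$data)
  flat <- matrix(aperm(eps$data, c(1, 2, 3)), d[1], d[2] * d[3])
  rec <- eeg_recording(flat, eps$rate, eps$channel_labels, eps$condition)
  write_edf(rec, file.path(dir, paste0(name, ".edf")))
  write_recording_text(rec, file.path(dir, paste0(name, ".csv")))
  manifest <- profile
  manifest$mixing <- NULL
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
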