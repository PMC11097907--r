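# Preprocessing chain: rereference -> downsample -> bandpass -> epoch ->
# subsample. Continuous recordings are `eeg_recording` objects (channels x
# samples matrix plus rate and labels); epoched data are `eeg_epochs`.

#' Construct a continuous multichannel recording
#'
#' @param data Channels x samples numeric matrix.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector of channel names.
#' @param condition Condition tag (e.g. "wake", "propofol", "synthetic").
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate,
                          channel_labels = paste0("ch", seq_len(nrow(data))),
                          condition = "unknown") {
  stopifnot(is.matrix(data), rate > 0,
            length(channel_labels) == nrow(data), all(is.finite(data)))
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 condition = condition),
            class = "eeg_recording")
}

#' Construct an epoched recording
#'
#' @param data Channels x samples x epochs numeric array.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector of channel names.
#' @param condition Condition tag.
#' @return Object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, rate,
                       channel_labels = paste0("ch", seq_len(dim(data)[1])),
                       condition = "unknown") {
  stopifnot(is.array(data), length(dim(data)) == 3, rate > 0,
            dim(data)[1] >= 2, all(is.finite(data)))
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 condition = condition),
            class = "eeg_epochs")
}

#' Bipolar re-reference
#'
#' Subtracts the difference signal `anode - cathode` from every channel
#' (bipolar derivation applied as a common reference). The reference
#' channels are retained and flagged in the `reference_channels` attribute.
#'
#' @param rec An `eeg_recording`.
#' @param anode,cathode Channel labels forming the bipolar pair.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, anode, cathode) {
  stopifnot(inherits(rec, "eeg_recording"))
  ia <- match(anode, rec$channel_labels)
  ic <- match(cathode, rec$channel_labels)
  if (is.na(ia) || is.na(ic)) stop("reference label not found")
  ref <- rec$data[ia, ] - rec$data[ic, ]
  out <- rec
  out$data <- sweep(rec$data, 2, ref, `-`)
  attr(out, "reference_channels") <- c(anode, cathode)
  out
}

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero-phase) application of a Butterworth bandpass.
#'
#' @param rec An `eeg_recording`, or a numeric matrix/vector with `rate`
#'   supplied.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order per edge (default 4).
#' @param rate Sampling rate, required for plain matrix/vector input.
#' @return Filtered object of the same kind as the input.
#' @export
bandpass <- function(rec, low = 0.5, high = 45, order = 4, rate = NULL) {
  if (inherits(rec, "eeg_recording")) {
    rate <- rec$rate
    x <- rec$data
  } else {
    stopifnot(!is.null(rate))
    x <- if (is.matrix(rec)) rec else matrix(rec, nrow = 1)
  }
  if (!(0 < low && low < high && high < rate / 2)) stop("invalid band")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  if (inherits(rec, "eeg_recording")) {
    rec$data <- y
    rec
  } else if (is.matrix(rec)) y else drop(y)
}

#' Anti-aliased downsampling
#'
#' Resamples to `target` Hz. Identity when `target` equals the current
#' rate; decimation with an anti-aliasing low-pass for integer factors;
#' polyphase resampling after an anti-aliasing filter otherwise.
#'
#' @param rec An `eeg_recording`.
#' @param target Target rate in Hz (must not exceed the current rate).
#' @return Downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target > rec$rate) stop("target rate above original rate")
  if (target == rec$rate) return(rec)
  # anti-aliasing low-pass at 80% of the new Nyquist, zero phase
  bf <- signal::butter(8, 0.8 * target / rec$rate, type = "low")
  filtered <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  ratio <- rec$rate / target
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(filtered), by = round(ratio))
    rec$data <- filtered[, idx, drop = FALSE]
  } else {
    p <- round(target); q <- round(rec$rate)
    if (abs(p - target) > 1e-9 || abs(q - rec$rate) > 1e-9)
      stop("non-integer rates require an integer decimation factor")
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    d <- g(p, q)
    rec$data <- t(apply(filtered, 1, function(ch)
      signal::resample(ch, p / d, q / d)))
  }
  rec$rate <- target
  rec
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Non-overlapping epochs of `length` seconds; a trailing remainder is
#' dropped. When a stimulus-onset table is supplied, epochs are instead
#' taken from the pre-stimulus windows `window` seconds relative to each
#' onset (mirroring analysis of stimulation-free data preceding each
#' pulse).
#'
#' @param rec An `eeg_recording`.
#' @param length Epoch length in seconds.
#' @param stimulus_onsets Optional numeric vector of stimulus times in
#'   seconds.
#' @param window Length-2 numeric: window relative to each onset in
#'   seconds (default `c(-5, -1)`).
#' @return An `eeg_epochs` object.
#' @export
epoch_recording <- function(rec, length = 4, stimulus_onsets = NULL,
                            window = c(-5, -1)) {
  stopifnot(inherits(rec, "eeg_recording"), length > 0)
  L <- round(length * rec$rate)
  if (is.null(stimulus_onsets)) {
    n_ep <- floor(ncol(rec$data) / L)
    if (n_ep < 1) stop("recording shorter than one epoch")
    starts <- (seq_len(n_ep) - 1) * L + 1
  } else {
    starts <- round((stimulus_onsets + window[1]) * rec$rate) + 1
    starts <- starts[starts >= 1 & (starts + L - 1) <= ncol(rec$data)]
    if (length(starts) < 1) stop("no complete pre-stimulus window available")
  }
  arr <- array(NA_real_, c(nrow(rec$data), L, length(starts)))
  for (e in seq_along(starts))
    arr[, , e] <- rec$data[, starts[e]:(starts[e] + L - 1)]
  eeg_epochs(arr, rec$rate, rec$channel_labels, rec$condition)
}

#' Randomly subsample channels and epochs
#'
#' Uniform sampling without replacement; the drawn indices are recorded in
#' the `subsample` attribute for provenance.
#'
#' @param epochs An `eeg_epochs`.
#' @param n_channels,n_epochs Numbers to retain.
#' @return Subsampled `eeg_epochs`.
#' @export
subsample_epochs <- function(epochs, n_channels, n_epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (n_channels > d[1] || n_epochs > d[3])
    stop("requested more channels or epochs than available")
  ch <- sort(sample.int(d[1], n_channels))
  ep <- sort(sample.int(d[3], n_epochs))
  out <- eeg_epochs(epochs$data[ch, , ep, drop = FALSE], epochs$rate,
                    epochs$channel_labels[ch], epochs$condition)
  attr(out, "subsample") <- list(channels = ch, epochs = ep)
  out
}

#' Full preprocessing chain
#'
#' Applies the documented order: rereference (optional) -> downsample ->
#' bandpass -> epoch -> subsample (optional).
#'
#' @param rec An `eeg_recording`.
#' @param anode,cathode Optional bipolar reference labels.
#' @param target_rate Rate after downsampling (Hz).
#' @param band Bandpass limits in Hz.
#' @param epoch_length Epoch length in seconds.
#' @param n_channels,n_epochs Optional subsampling sizes.
#' @param stimulus_onsets Optional stimulus table for pre-stimulus epochs.
#' @return An `eeg_epochs` object.
#' @export
preprocess_recording <- function(rec, anode = NULL, cathode = NULL,
                                 target_rate = 500, band = c(0.5, 45),
                                 epoch_length = 4,
                                 n_channels = NULL, n_epochs = NULL,
                                 stimulus_onsets = NULL) {
  if (!is.null(anode) && !is.null(cathode))
    rec <- rereference(rec, anode, cathode)
  rec <- downsample(rec, target_rate)
  rec <- bandpass(rec, band[1], band[2])
  eps <- epoch_recording(rec, epoch_length, stimulus_onsets)
  if (!is.null(n_channels) || !is.null(n_epochs)) {
    d <- dim(eps$data)
    eps <- subsample_epochs(eps,
                            if (is.null(n_channels)) d[1] else n_channels,
                            if (is.null(n_epochs)) d[3] else n_epochs)
  }
  eps
}

#' Amplitude-threshold bad-channel helper
#'
#' Flags channels whose peak absolute amplitude exceeds `threshold`. Off by
#' default in the pipeline; bad channels are otherwise supplied as a manual
#' list.
#'
#' @param rec An `eeg_recording`.
#' @param threshold Amplitude threshold (same units as the data).
#' @return Integer vector of flagged channel indices.
#' @export
flag_bad_channels <- function(rec, threshold) {
  which(apply(abs(rec$data), 1, max) > threshold)
}

#' Read a delimited-text recording
#'
#' Expects a header-free delimited file with one row per channel.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz.
#' @param sep Field separator.
#' @param ... Passed to [eeg_recording()].
#' @return An `eeg_recording`.
#' @export
read_recording_text <- function(path, rate, sep = ",", ...) {
  m <- as.matrix(read.csv(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  eeg_recording(m, rate, ...)
}

#' Write a recording as delimited text
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path, sep = ",") {
  write.table(rec$data, path, sep = sep, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
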