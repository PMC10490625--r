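# Preprocessing: mains notch, ICA-based artifact removal against reference
# channels, epoch segmentation, and SNR-based epoch rejection. The cleaning
# order used by the pipeline is fixed: band-stop -> ICA -> SNR rejection ->
# band-pass.

#' Filter specification
#'
#' @param kind `"band_stop"` or `"band_pass"`.
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high < Nyquist`.
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase Apply forward-backward (zero-phase) filtering.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("band_pass", "band_stop"), f_low, f_high,
                        order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  stopifnot_scalar_number(f_low, "f_low", lower = 1e-12)
  stopifnot_scalar_number(f_high, "f_high", lower = f_low + 1e-12)
  stopifnot_scalar_number(order, "order", lower = 1)
  structure(list(kind = kind, f_low = f_low, f_high = f_high,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply a band filter to every channel of a recording
#'
#' Filtering is zero-phase (forward-backward) by default, so annotation and
#' epoch timing are preserved; shape and annotations are untouched.
#'
#' @param recording A [raw_recording()].
#' @param spec A [filter_spec()].
#' @return A new `raw_recording` with filtered samples.
#' @export
apply_filter <- function(recording, spec) {
  stopifnot(inherits(recording, "raw_recording"),
            inherits(spec, "filter_spec"))
  nyq <- recording$sampling_rate_hz / 2
  if (spec$f_high >= nyq)
    stop("filter edge ", spec$f_high, " Hz at or above Nyquist (", nyq,
         " Hz)")
  w <- c(spec$f_low, spec$f_high) / nyq
  flt <- signal::butter(spec$order, w,
                        type = if (spec$kind == "band_stop") "stop"
                               else "pass")
  out <- recording
  for (i in seq_len(nrow(out$samples))) {
    out$samples[i, ] <- if (spec$zero_phase)
      signal::filtfilt(flt, out$samples[i, ])
    else as.numeric(signal::filter(flt, out$samples[i, ]))
  }
  out
}

# FastICA (hyperbolic-tangent contrast, symmetric orthogonalization).
# Unmixing is estimated on a column subsample for speed and applied to the
# full data; deterministic given `seed`.
fast_ica <- function(X, seed = 1, max_iter = 200, tol = 1e-6,
                     max_fit_samples = 100000L) {
  nc <- nrow(X)
  center <- rowMeans(X)
  Xc <- X - center
  with_seed(seed, {
    fit_cols <- if (ncol(Xc) > max_fit_samples)
      sort(sample.int(ncol(Xc), max_fit_samples)) else seq_len(ncol(Xc))
    Xf <- Xc[, fit_cols, drop = FALSE]
    cv <- stats::cov(t(Xf))
    eg <- eigen(cv, symmetric = TRUE)
    if (any(eg$values < 1e-12 * max(eg$values)))
      stop("decomposition error: rank-deficient data (fewer independent ",
           "samples than channels)")
    K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitening
    Z <- K %*% Xf
    W <- matrix(stats::rnorm(nc * nc), nc, nc)
    sym_decorrelate <- function(W) {
      s <- La.svd(W)
      s$u %*% s$vt
    }
    W <- sym_decorrelate(W)
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      gprime <- rowMeans(1 - G^2)
      W1 <- (G %*% t(Z)) / ncol(Z) - diag(gprime) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) break
    }
  })
  unmix <- W %*% K                 # sources = unmix %*% centered data
  mix <- solve(unmix)              # channels = mix %*% sources
  list(sources = unmix %*% Xc, mixing = mix, unmixing = unmix,
       center = center)
}

#' Remove artifact components by ICA against reference channels
#'
#' Decomposes the (non-reference) EEG channels with FastICA; any
#' independent component whose absolute Pearson correlation with any named
#' reference channel exceeds `correlation_threshold` is zeroed before
#' remixing back to channel space. With no reference channels the recording
#' is returned unchanged with a warning.
#'
#' @param recording A [raw_recording()].
#' @param reference_labels Channel labels used as artifact references
#'   (e.g. `c("EOG", "EMG")`); may be empty.
#' @param correlation_threshold Absolute-correlation cutoff (default 0.7).
#' @param seed Seed for the ICA initialization (default 1).
#' @return A new `raw_recording` with artifact components removed from the
#'   EEG channels; reference channels are passed through untouched.
#' @export
remove_artifact_components <- function(recording,
                                       reference_labels =
                                         intersect(REFERENCE_CHANNELS,
                                                   recording$channel_labels),
                                       correlation_threshold = 0.7,
                                       seed = 1) {
  stopifnot(inherits(recording, "raw_recording"))
  if (!length(reference_labels)) {
    warning("no reference channels given; returning recording unchanged")
    return(recording)
  }
  missing <- setdiff(reference_labels, recording$channel_labels)
  if (length(missing))
    stop("reference channel(s) not in recording: ",
         paste(missing, collapse = ", "))
  eeg <- setdiff(recording$channel_labels, reference_labels)
  if (length(eeg) < 2)
    stop("need at least 2 EEG channels for ICA")
  X <- recording$samples[eeg, , drop = FALSE]
  if (ncol(X) < nrow(X))
    stop("decomposition error: fewer samples than channels")
  ica <- fast_ica(X, seed = seed)
  refs <- recording$samples[reference_labels, , drop = FALSE]
  cors <- abs(stats::cor(t(ica$sources), t(refs)))
  drop_idx <- which(apply(cors, 1, max) > correlation_threshold)
  log_stage("ica", sprintf("removing %d/%d components (|r| > %.2f)",
                           length(drop_idx), nrow(X),
                           correlation_threshold))
  S <- ica$sources
  if (length(drop_idx)) S[drop_idx, ] <- 0
  cleaned <- ica$mixing %*% S + ica$center
  out <- recording
  out$samples[eeg, ] <- cleaned
  out
}

#' Labeled fixed-length epochs
#'
#' Container produced by [segment_epochs()]: a channels x samples x epochs
#' array plus per-epoch activity labels, start times, SNR estimates and
#' keep flags.
#' @name epoch_set
NULL

new_epoch_set <- function(data, labels, start_s, epoch_length_s,
                          sampling_rate_hz, channel_labels,
                          snr_db = rep(NA_real_, length(labels)),
                          kept = rep(TRUE, length(labels)),
                          snr_threshold_db = NA_real_) {
  structure(list(data = data, labels = labels, start_s = start_s,
                 epoch_length_s = epoch_length_s,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = channel_labels, snr_db = snr_db,
                 kept = kept, snr_threshold_db = snr_threshold_db),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              length(x$labels), length(x$channel_labels),
              dim(x$data)[2], x$epoch_length_s, x$sampling_rate_hz))
  cat(sprintf(" kept %d / %d\n", sum(x$kept), length(x$kept)))
  invisible(x)
}

#' Cut annotated intervals into fixed-length epochs
#'
#' Each annotated interval is cut into consecutive non-overlapping epochs
#' of exactly `epoch_length_s` seconds; a trailing remainder shorter than
#' one epoch is dropped. Each epoch carries its interval's activity label.
#'
#' @param recording A [raw_recording()] with annotations.
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @return An [epoch_set].
#' @export
segment_epochs <- function(recording, epoch_length_s = 10) {
  stopifnot(inherits(recording, "raw_recording"))
  stopifnot_scalar_number(epoch_length_s, "epoch_length_s", lower = 1e-9)
  fs <- recording$sampling_rate_hz
  n_ep <- round(epoch_length_s * fs)
  ann <- recording$annotations
  if (!nrow(ann)) {
    warning("recording has no annotations; returning empty epoch set")
    return(new_epoch_set(array(0, c(nrow(recording$samples), n_ep, 0)),
                         character(0), numeric(0), epoch_length_s, fs,
                         recording$channel_labels))
  }
  starts <- numeric(0); labels <- character(0)
  for (i in seq_len(nrow(ann))) {
    n_fit <- floor((ann$end_s[i] - ann$start_s[i]) / epoch_length_s + 1e-9)
    if (n_fit < 1) next
    starts <- c(starts, ann$start_s[i] + (seq_len(n_fit) - 1) *
                  epoch_length_s)
    labels <- c(labels, rep(ann$activity[i], n_fit))
  }
  data <- array(0, c(nrow(recording$samples), n_ep, length(starts)),
                dimnames = list(recording$channel_labels, NULL, NULL))
  for (e in seq_along(starts)) {
    i0 <- round(starts[e] * fs) + 1L
    data[, , e] <- recording$samples[, i0:(i0 + n_ep - 1L)]
  }
  new_epoch_set(data, labels, starts, epoch_length_s, fs,
                recording$channel_labels)
}

# One-sided periodogram band power (mean power in [lo, hi] Hz) of a vector.
periodogram_power <- function(x, fs, lo, hi, half_open_low = TRUE) {
  n <- length(x)
  p <- abs(stats::fft(x))^2 / n^2            # power per bin, two-sided
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  sel <- if (half_open_low) freqs > lo & freqs <= hi
         else freqs >= lo & freqs <= hi
  sum(p[sel])
}

#' Estimate per-epoch SNR and flag rejections
#'
#' SNR(dB) = 10 log10(P_in / P_out), where P_in is the mean per-EEG-channel
#' power inside the analysis band (0.5--44 Hz) and P_out the mean power
#' above 44 Hz up to Nyquist, both computed from the epoch's periodogram on
#' the signal as given (i.e. before any band-pass filtering). Epochs with
#' no out-of-band power get SNR `+Inf` and are kept. Reference channels are
#' excluded from the estimate because they deliberately carry artifacts.
#'
#' @param epochs An [epoch_set].
#' @param threshold_db Rejection threshold in dB (default 25).
#' @param in_band Analysis band c(lo, hi) in Hz (default `c(0.5, 44)`).
#' @return The epoch set with `snr_db` filled in and `kept` set to
#'   `snr_db >= threshold_db`.
#' @export
estimate_snr_and_reject <- function(epochs, threshold_db = 25,
                                    in_band = c(0.5, 44)) {
  stopifnot(inherits(epochs, "epoch_set"))
  stopifnot_scalar_number(threshold_db, "threshold_db")
  n_epochs <- length(epochs$labels)
  if (!n_epochs) stop("empty epoch set")
  fs <- epochs$sampling_rate_hz
  eeg <- intersect(epochs$channel_labels, EEG_CHANNELS)
  if (!length(eeg)) eeg <- epochs$channel_labels
  snr <- numeric(n_epochs)
  for (e in seq_len(n_epochs)) {
    pin <- mean(vapply(eeg, function(ch)
      periodogram_power(epochs$data[ch, , e], fs, in_band[1], in_band[2],
                        half_open_low = FALSE), numeric(1)))
    pout <- mean(vapply(eeg, function(ch)
      periodogram_power(epochs$data[ch, , e], fs, in_band[2], fs / 2),
      numeric(1)))
    snr[e] <- if (pout <= 0) Inf else 10 * log10(pin / pout)
  }
  kept <- snr >= threshold_db
  log_stage("snr", sprintf("kept %d, rejected %d of %d epochs (threshold %g dB)",
                           sum(kept), sum(!kept), n_epochs, threshold_db))
  epochs$snr_db <- snr
  epochs$kept <- kept
  epochs$snr_threshold_db <- threshold_db
  epochs
}

#' Run the full preprocessing chain on a recording
#'
#' Fixed stage order: 60 Hz band-stop, ICA artifact removal against the
#' available reference channels, segmentation into epochs, SNR-based epoch
#' rejection, then the 0.5--44 Hz band-pass applied to the kept epochs.
#'
#' @param recording A [raw_recording()].
#' @param notch_hz Mains frequency (default 60).
#' @param band_pass Analysis band c(lo, hi) in Hz (default `c(0.5, 44)`).
#' @param snr_threshold_db Epoch-rejection threshold (default 25).
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param correlation_threshold ICA reference-correlation cutoff.
#' @param ica_seed Seed for the ICA initialization.
#' @return An [epoch_set] with SNR flags set and kept epochs band-passed.
#' @export
preprocess_recording <- function(recording, notch_hz = 60,
                                 band_pass = c(0.5, 44),
                                 snr_threshold_db = 25,
                                 epoch_length_s = 10,
                                 correlation_threshold = 0.7,
                                 ica_seed = 1) {
  log_stage("preprocess", "band-stop ", notch_hz, " Hz")
  rec <- apply_filter(recording,
                      filter_spec("band_stop", notch_hz - 3, notch_hz + 3))
  refs <- intersect(REFERENCE_CHANNELS, rec$channel_labels)
  if (length(refs)) {
    log_stage("preprocess", "ICA artifact removal vs ",
              paste(refs, collapse = ", "))
    rec <- remove_artifact_components(rec, refs, correlation_threshold,
                                      seed = ica_seed)
  } else {
    log_stage("preprocess", "no reference channels; skipping ICA")
  }
  epochs <- segment_epochs(rec, epoch_length_s)
  epochs <- estimate_snr_and_reject(epochs, snr_threshold_db, band_pass)
  # band-pass the kept epochs, applied after rejection so the SNR estimate
  # sees the out-of-band noise it screens for; an ideal zero-phase
  # (frequency-domain) filter avoids the band-edge attenuation an IIR
  # filter would impose on the gamma band right below the 44 Hz cutoff
  for (e in which(epochs$kept))
    epochs$data[, , e] <- fft_bandpass(epochs$data[, , e],
                                       epochs$sampling_rate_hz,
                                       band_pass[1], band_pass[2])
  epochs
}

# Ideal zero-phase band-pass: zero all DFT bins outside [lo, hi] Hz.
# Operates row-wise on a channels x samples matrix.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- ncol(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  mask <- freqs >= lo & freqs <= hi
  X <- t(stats::mvfft(t(x)))
  X[, !mask] <- 0
  out <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
  dimnames(out) <- dimnames(x)
  out
}
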