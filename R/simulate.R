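# Synthetic multichannel EEG with known activity-dependent spectral
# structure. Band components are synthesized directly in the frequency
# domain (Gaussian Fourier coefficients confined to the band, i.e. ideal
# zero-phase band-pass-filtered white noise), so each epoch attains its
# profile's band-power fractions exactly at DFT resolution and carries no
# out-of-band leakage.

# Gaussian noise confined to [f_low, f_high) Hz, length n at rate fs,
# scaled to unit standard deviation. Returns one column per requested
# realization; `shared` mixes a common realization into every column with
# variance fraction `rho` (used for homologous channel pairs).
band_noise <- function(n, fs, f_low, f_high, ncol = 1L, rho = 0) {
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)            # alias to physical frequency
  in_band <- freqs >= f_low & freqs < f_high & seq_len(n) <= (n %/% 2 + 1)
  idx <- which(in_band & freqs > 0)
  out <- matrix(0, n, ncol)
  if (!length(idx)) return(out)
  m <- length(idx)
  make_coef <- function() complex(real = stats::rnorm(m),
                                  imaginary = stats::rnorm(m))
  common <- make_coef()
  for (j in seq_len(ncol)) {
    coef <- sqrt(rho) * common + sqrt(1 - rho) * make_coef()
    spec <- complex(real = rep(0, n))
    spec[idx] <- coef
    mirror <- n - idx + 2L                     # Hermitian counterpart
    ok <- mirror >= 1L & mirror <= n & mirror != idx
    spec[mirror[ok]] <- Conj(coef[ok])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    s <- stats::sd(x)
    out[, j] <- if (s > 0) x / s else x
  }
  out
}

# Smooth blink-like transient: raised-cosine bump, `dur_s` long.
blink_waveform <- function(fs, dur_s = 0.4) {
  n <- max(2L, round(dur_s * fs))
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Generate a synthetic multichannel EEG recording
#'
#' Produces a continuous recording in which each activity contributes
#' `epochs_per_activity` contiguous annotated epochs. Within an epoch,
#' every EEG channel is a sum of five band-limited Gaussian components
#' whose variances attain the channel's region target relative band powers
#' exactly, plus (as configured) a 60 Hz mains sinusoid, blink-like
#' transients mixed most strongly into Fz and the EOG reference, broadband
#' 30--100 Hz muscle bursts mixed into T7/T8 and the EMG reference, and —
#' in a chosen fraction of epochs — high-amplitude broadband motion noise
#' that pushes the epoch's SNR below the 25 dB rejection threshold.
#'
#' The output is bit-reproducible given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A [raw_recording()] whose `ground_truth` records, per epoch, the
#'   generating activity and whether motion noise was injected, plus the
#'   artifact source time courses.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$sampling_rate_hz
  n_ep <- round(config$epoch_length_s * fs)
  acts <- names(config$epochs_per_activity)
  counts <- as.integer(config$epochs_per_activity)
  total_epochs <- sum(counts)
  n_total <- total_epochs * n_ep
  channels <- EEG_CHANNELS
  if (config$include_reference_channels)
    channels <- c(channels, REFERENCE_CHANNELS)

  with_seed(config$seed, {
    samples <- matrix(0, length(channels), n_total,
                      dimnames = list(channels, NULL))
    epoch_activity <- rep(acts, counts)
    rho <- config$homologous_correlation
    bands <- eeg_bands()
    right_scale <- sqrt(config$asymmetry)

    rs <- config$region_amplitude_scale
    for (e in seq_len(total_epochs)) {
      prof <- config$profiles[[epoch_activity[e]]]
      cols <- ((e - 1L) * n_ep + 1L):(e * n_ep)
      amp2 <- prof$amplitude_uV^2
      for (b in seq_len(nrow(bands))) {
        lo <- bands$f_low[b]; hi <- bands$f_high[b]; bn <- bands$name[b]
        # singleton regions
        sdF <- rs[["F"]] * sqrt(amp2 * prof$target_rp$F[[bn]])
        sdO <- rs[["O"]] * sqrt(amp2 * prof$target_rp$O[[bn]])
        samples["Fz", cols] <- samples["Fz", cols] +
          sdF * band_noise(n_ep, fs, lo, hi)
        samples["Oz", cols] <- samples["Oz", cols] +
          sdO * band_noise(n_ep, fs, lo, hi)
        # homologous pairs share a common source fraction rho
        sdC <- rs[["C"]] * sqrt(amp2 * prof$target_rp$C[[bn]])
        cc <- band_noise(n_ep, fs, lo, hi, ncol = 2L, rho = rho)
        samples["C1", cols] <- samples["C1", cols] + sdC * cc[, 1]
        samples["C2", cols] <- samples["C2", cols] +
          right_scale * sdC * cc[, 2]
        sdT <- rs[["T"]] * sqrt(amp2 * prof$target_rp$T[[bn]])
        tt <- band_noise(n_ep, fs, lo, hi, ncol = 2L, rho = rho)
        samples["T7", cols] <- samples["T7", cols] + sdT * tt[, 1]
        samples["T8", cols] <- samples["T8", cols] +
          right_scale * sdT * tt[, 2]
      }
    }

    tgrid <- seq_len(n_total) / fs
    if (config$mains_amplitude_uV > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      mains <- config$mains_amplitude_uV * sin(2 * pi * 60 * tgrid + phase)
      samples <- sweep(samples, 2, mains, `+`)
    }

    dur_s <- n_total / fs
    blink_source <- numeric(n_total)
    if (config$blink_rate_per_min > 0) {
      n_blinks <- stats::rpois(1, config$blink_rate_per_min * dur_s / 60)
      wav <- config$blink_amplitude_uV * blink_waveform(fs)
      starts <- sort(stats::runif(n_blinks, 0, dur_s - length(wav) / fs))
      for (s0 in starts) {
        i0 <- round(s0 * fs) + 1L
        span <- i0:(i0 + length(wav) - 1L)
        blink_source[span] <- blink_source[span] + wav
      }
      blink_gain <- stats::setNames(rep(0.05, length(channels)), channels)
      blink_gain["Fz"] <- 1
      blink_gain[c("C1", "C2")] <- 0.3
      if ("EOG" %in% channels) blink_gain["EOG"] <- 2
      samples <- samples + outer(blink_gain, blink_source)
    }

    emg_source <- numeric(n_total)
    if (config$emg_burst_rate_per_min > 0) {
      n_bursts <- stats::rpois(1, config$emg_burst_rate_per_min * dur_s / 60)
      burst_n <- round(0.5 * fs)
      env <- blink_waveform(fs, 0.5)[seq_len(burst_n)]
      starts <- sort(stats::runif(n_bursts, 0, dur_s - burst_n / fs))
      for (s0 in starts) {
        i0 <- round(s0 * fs) + 1L
        span <- i0:(i0 + burst_n - 1L)
        burst <- band_noise(burst_n, fs, 30, min(100, fs / 2))[, 1] * env
        emg_source[span] <- emg_source[span] +
          config$emg_amplitude_uV * burst
      }
      # one-sided temporal muscle (e.g. left temporalis): strong on T7,
      # weak on T8, so the source direction is distinct from the shared
      # left/right background component
      emg_gain <- stats::setNames(rep(0.05, length(channels)), channels)
      emg_gain["T7"] <- 1
      emg_gain["T8"] <- 0.1
      if ("EMG" %in% channels) emg_gain["EMG"] <- 2
      samples <- samples + outer(emg_gain, emg_source)
    }

    motion_epochs <- integer(0)
    if (config$motion_epoch_fraction > 0) {
      n_motion <- round(config$motion_epoch_fraction * total_epochs)
      motion_epochs <- sort(sample.int(total_epochs, n_motion))
      for (e in motion_epochs) {
        cols <- ((e - 1L) * n_ep + 1L):(e * n_ep)
        amp <- config$profiles[[epoch_activity[e]]]$amplitude_uV
        noise_sd <- config$motion_noise_gain * amp
        samples[, cols] <- samples[, cols] +
          matrix(stats::rnorm(length(channels) * n_ep, sd = noise_sd),
                 length(channels), n_ep)
      }
    }

    ann <- data.frame(
      start_s = (seq_len(total_epochs) - 1) * config$epoch_length_s,
      end_s = seq_len(total_epochs) * config$epoch_length_s,
      activity = epoch_activity,
      stringsAsFactors = FALSE
    )
    raw_recording(
      samples = samples, sampling_rate_hz = fs, annotations = ann,
      ground_truth = list(
        epoch_activity = epoch_activity,
        motion_epochs = motion_epochs,
        profiles = config$profiles,
        blink_source = blink_source,
        emg_source = emg_source,
        config = config
      )
    )
  })
}
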