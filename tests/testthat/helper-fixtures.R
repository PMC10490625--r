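# Shared fixtures: all built in code at test time.

# Small, artifact-free simulation: fast and exactly recoverable.
clean_config <- function(n = 4, seed = 1, ...) {
  simulation_config(
    epochs_per_activity = c(reading = n, walking = n, working = n,
                            resting = n),
    mains_amplitude_uV = 0, blink_rate_per_min = 0,
    emg_burst_rate_per_min = 0, motion_epoch_fraction = 0,
    include_reference_channels = FALSE, seed = seed, ...)
}

# Small simulation with the default artifact plumbing switched on.
noisy_config <- function(n = 6, seed = 1, ...) {
  simulation_config(
    epochs_per_activity = c(reading = n, walking = n, working = n,
                            resting = n),
    seed = seed, ...)
}

# Well-separated Gaussian feature table for model-level tests: class means
# differ by `gap` standard deviations on the first `informative` features.
make_separable_table <- function(n_per_class = 30, n_features = 6,
                                 informative = 3, gap = 6, seed = 1,
                                 classes = activity_classes()) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      X <- matrix(rnorm(n_per_class * n_features), n_per_class)
      k <- min(informative, n_features)
      X[, seq_len(k)] <- sweep(X[, seq_len(k), drop = FALSE], 2,
                               gap * ci * seq_len(k) / k, `+`)
      X
    })
    X <- do.call(rbind, rows)
    colnames(X) <- paste0("feat", seq_len(n_features))
    df <- as.data.frame(X)
    df$label <- factor(rep(classes, each = n_per_class))
    df
  })
}

# Flat unit-PSD spectrum on a 0.5 Hz grid covering 0-Nyquist, one channel.
flat_spectrum <- function(value = 1, fs = 250, df = 0.5) {
  freqs <- seq(0, fs / 2, by = df)
  psd <- matrix(value, 1, length(freqs), dimnames = list("Fz", NULL))
  structure(list(frequencies = freqs, psd = psd, sampling_rate_hz = fs,
                 welch_params = welch_params()),
            class = "spectrum_estimate")
}
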