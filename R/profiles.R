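#' Construct an activity spectral profile
#'
#' An `activity_profile` is the simulator's ground truth for one activity:
#' for each scalp region it fixes the fraction of signal power in each of
#' the five EEG bands, plus an overall RMS amplitude in microvolts.
#'
#' @param activity One of `activity_classes()`.
#' @param target_rp Named list `region -> named numeric vector of band
#'   fractions` for regions F, C, T, O and bands Delta...Gamma. Each
#'   region's fractions must be nonnegative and sum to 1 (tolerance 1e-9).
#' @param amplitude_uV Channel RMS amplitude in microvolts.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(activity, target_rp, amplitude_uV = 30) {
  if (!is.character(activity) || length(activity) != 1L)
    stop("`activity` must be a single label")
  if (!setequal(names(target_rp), REGION_NAMES))
    stop("configuration error: profile regions must be exactly ",
         paste(REGION_NAMES, collapse = ", "), "; got ",
         paste(names(target_rp), collapse = ", "))
  for (r in REGION_NAMES) {
    v <- target_rp[[r]]
    if (!setequal(names(v), BAND_NAMES))
      stop("configuration error: unknown or missing band key in region '",
           r, "': ", paste(setdiff(union(names(v), BAND_NAMES),
                                   intersect(names(v), BAND_NAMES)),
                           collapse = ", "))
    v <- v[BAND_NAMES]
    if (any(v < 0)) stop("negative relative power in region '", r, "'")
    if (abs(sum(v) - 1) > 1e-9)
      stop("relative powers in region '", r, "' sum to ", sum(v), ", not 1")
    target_rp[[r]] <- v
  }
  stopifnot_scalar_number(amplitude_uV, "amplitude_uV", lower = 0)
  structure(list(activity = activity, target_rp = target_rp[REGION_NAMES],
                 amplitude_uV = amplitude_uV),
            class = "activity_profile")
}

#' Default activity profiles
#'
#' Four well-separated spectral signatures, one per activity, chosen to
#' echo the qualitative band/region contrasts the analysis is designed to
#' detect: resting shows high alpha (especially occipital) and low central
#' beta; reading (a cognitive task) shows reduced frontal alpha, reduced
#' central beta and the lowest central gamma; walking (motor) shows raised
#' frontal theta, occipital alpha and central beta; working (a manual task)
#' is defined chiefly by strongly elevated central — and hence global —
#' gamma with reduced central beta.
#'
#' @return Named list of four `activity_profile` objects.
#' @export
default_activity_profiles <- function() {
  rp <- function(d, t, a, b, g)
    stats::setNames(c(d, t, a, b, g), BAND_NAMES)
  list(
    reading = activity_profile("reading", list(
      F = rp(.28, .26, .18, .20, .08),
      C = rp(.26, .24, .30, .15, .05),
      T = rp(.24, .24, .28, .16, .08),
      O = rp(.20, .18, .36, .18, .08))),
    resting = activity_profile("resting", list(
      F = rp(.22, .20, .34, .16, .08),
      C = rp(.22, .18, .34, .18, .08),
      T = rp(.22, .22, .30, .18, .08),
      O = rp(.16, .14, .44, .18, .08))),
    walking = activity_profile("walking", list(
      F = rp(.20, .30, .26, .16, .08),
      C = rp(.18, .18, .28, .28, .08),
      T = rp(.22, .20, .30, .20, .08),
      O = rp(.12, .12, .52, .16, .08))),
    working = activity_profile("working", list(
      F = rp(.22, .20, .34, .16, .08),
      C = rp(.15, .14, .25, .14, .32),
      T = rp(.22, .22, .30, .18, .08),
      O = rp(.16, .14, .44, .18, .08)))
  )
}

#' Simulation configuration
#'
#' Bundles everything `generate_recording()` needs. Defaults reproduce the
#' study-scale dataset: 793 reading, 408 walking, 267 working and 243
#' resting 10-s epochs at 250 Hz, with 60 Hz mains contamination, blink and
#' muscle artifact sources mirrored on EOG/EMG reference channels, and an
#' optional fraction of motion-corrupted (low-SNR) epochs.
#'
#' @param profiles List of `activity_profile`s (default
#'   `default_activity_profiles()`).
#' @param epochs_per_activity Named integer vector, epochs per activity.
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param sampling_rate_hz Sampling rate in Hz (default 250; must be at
#'   least 88 Hz so the gamma edge at 44 Hz stays below Nyquist).
#' @param mains_amplitude_uV Amplitude of the 60 Hz mains sinusoid (µV).
#' @param blink_rate_per_min Blink-like transient rate (events/min).
#' @param emg_burst_rate_per_min Muscle-burst rate (events/min).
#' @param motion_epoch_fraction Fraction of epochs corrupted with
#'   high-amplitude broadband noise so their SNR falls below the 25 dB
#'   rejection threshold. Default 0: the default dataset is the post-
#'   rejection composition, so every epoch survives preprocessing.
#' @param asymmetry Variance scale applied to the right channel of each
#'   homologous pair (C2, T8). 1 = symmetric; values > 1 create a known
#'   left/right asymmetry for brain-symmetry-index tests.
#' @param homologous_correlation Fraction of band-component variance shared
#'   between the two channels of a homologous pair; high values keep the
#'   symmetry index of artifact-free data low, as in a common-source scalp
#'   montage.
#' @param include_reference_channels Add EOG and EMG reference channels
#'   carrying the blink and muscle sources (needed for ICA-based removal).
#' @param region_amplitude_scale Named multipliers on `amplitude_uV` per
#'   region, mimicking typical scalp topography: occipital largest,
#'   central (vertex) smallest. Relative band powers are per-region
#'   normalized and therefore unaffected; only absolute channel
#'   amplitudes differ.
#' @param blink_amplitude_uV,emg_amplitude_uV Artifact source amplitudes.
#' @param motion_noise_gain Motion-noise standard deviation as a multiple
#'   of the channel RMS amplitude.
#' @param seed Integer RNG seed; the whole recording is deterministic in it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(profiles = default_activity_profiles(),
                              epochs_per_activity = c(reading = 793,
                                                      walking = 408,
                                                      working = 267,
                                                      resting = 243),
                              epoch_length_s = 10,
                              sampling_rate_hz = 250,
                              mains_amplitude_uV = 5,
                              blink_rate_per_min = 12,
                              emg_burst_rate_per_min = 10,
                              motion_epoch_fraction = 0,
                              asymmetry = 1,
                              homologous_correlation = 0.9,
                              include_reference_channels = TRUE,
                              region_amplitude_scale = c(F = 1.2, C = 0.4,
                                                         T = 1.2, O = 1.4),
                              blink_amplitude_uV = 300,
                              emg_amplitude_uV = 350,
                              motion_noise_gain = 2,
                              seed = 1) {
  stopifnot_scalar_number(epoch_length_s, "epoch_length_s", lower = 1e-9)
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 88)
  stopifnot_scalar_number(mains_amplitude_uV, "mains_amplitude_uV", lower = 0)
  stopifnot_scalar_number(blink_rate_per_min, "blink_rate_per_min", lower = 0)
  stopifnot_scalar_number(emg_burst_rate_per_min, "emg_burst_rate_per_min",
                          lower = 0)
  stopifnot_scalar_number(motion_epoch_fraction, "motion_epoch_fraction",
                          lower = 0, upper = 1)
  stopifnot_scalar_number(asymmetry, "asymmetry", lower = 0)
  stopifnot_scalar_number(homologous_correlation, "homologous_correlation",
                          lower = 0, upper = 1)
  if (!setequal(names(region_amplitude_scale), REGION_NAMES) ||
      any(region_amplitude_scale <= 0))
    stop("region_amplitude_scale needs positive entries for ",
         paste(REGION_NAMES, collapse = ", "))
  prof_names <- vapply(profiles, function(p) p$activity, character(1))
  names(profiles) <- prof_names
  if (!all(names(epochs_per_activity) %in% prof_names))
    stop("configuration error: no profile for activity ",
         paste(setdiff(names(epochs_per_activity), prof_names),
               collapse = ", "))
  if (any(epochs_per_activity < 0))
    stop("epoch counts must be nonnegative")
  structure(list(
    profiles = profiles,
    epochs_per_activity = epochs_per_activity,
    epoch_length_s = epoch_length_s,
    sampling_rate_hz = sampling_rate_hz,
    mains_amplitude_uV = mains_amplitude_uV,
    blink_rate_per_min = blink_rate_per_min,
    emg_burst_rate_per_min = emg_burst_rate_per_min,
    motion_epoch_fraction = motion_epoch_fraction,
    asymmetry = asymmetry,
    homologous_correlation = homologous_correlation,
    include_reference_channels = isTRUE(include_reference_channels),
    region_amplitude_scale = region_amplitude_scale[REGION_NAMES],
    blink_amplitude_uV = blink_amplitude_uV,
    emg_amplitude_uV = emg_amplitude_uV,
    motion_noise_gain = motion_noise_gain,
    seed = as.integer(seed)
  ), class = "simulation_config")
}
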