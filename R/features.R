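# Spectral feature extraction: Welch PSD, band powers with region
# averaging, relative band power, pairwise-derived brain symmetry index
# (pdBSI) and the DAR/DTR/DTABR power ratios.

#' Welch estimator parameters
#'
#' @param segment_length_s Segment length in seconds. The 2 s default gives
#'   0.5 Hz resolution, resolving the 0.5 Hz delta edge.
#' @param overlap_fraction Fractional overlap between segments (default
#'   0.1, i.e. 10 percent).
#' @param taper Taper name; only `"hamming"` is implemented.
#' @return A list of class `welch_params`.
#' @export
welch_params <- function(segment_length_s = 2, overlap_fraction = 0.1,
                         taper = "hamming") {
  stopifnot_scalar_number(segment_length_s, "segment_length_s",
                          lower = 1e-9)
  stopifnot_scalar_number(overlap_fraction, "overlap_fraction", lower = 0,
                          upper = 0.99)
  if (!identical(taper, "hamming")) stop("only the Hamming taper is supported")
  structure(list(segment_length_s = segment_length_s,
                 overlap_fraction = overlap_fraction, taper = taper),
            class = "welch_params")
}

#' Welch power spectral density of one epoch
#'
#' Averaged modified periodogram with a Hamming taper per segment, scaled
#' so the one-sided PSD integrates (trapezoid over 0--Nyquist) to the
#' signal's mean square power (Parseval, up to taper correction).
#'
#' @param epoch Channels x samples numeric matrix (rownames = channels) or
#'   a numeric vector for a single channel.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param params A [welch_params()].
#' @return List of class `spectrum_estimate` with `frequencies` (Hz) and
#'   `psd` (channels x frequencies, µV²/Hz).
#' @export
welch_psd <- function(epoch, sampling_rate_hz, params = welch_params()) {
  if (is.vector(epoch)) epoch <- matrix(epoch, 1,
                                        dimnames = list("x", NULL))
  fs <- sampling_rate_hz
  seg <- round(params$segment_length_s * fs)
  n <- ncol(epoch)
  if (seg > n) stop("Welch segment (", seg, " samples) longer than epoch (",
                    n, " samples)")
  step <- max(1L, round(seg * (1 - params$overlap_fraction)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- signal::hamming(seg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- seg %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1) * fs / seg
  psd <- matrix(0, nrow(epoch), nfreq,
                dimnames = list(rownames(epoch), NULL))
  for (s0 in starts) {
    segm <- epoch[, s0:(s0 + seg - 1L), drop = FALSE]
    segm <- segm - rowMeans(segm)            # per-segment demeaning
    X <- stats::mvfft(t(segm * rep(w, each = nrow(segm))))
    p <- abs(X[seq_len(nfreq), , drop = FALSE])^2 * scale
    p[2:(nfreq - 1L), ] <- 2 * p[2:(nfreq - 1L), ]   # one-sided
    psd <- psd + t(p)
  }
  psd <- psd / length(starts)
  structure(list(frequencies = freqs, psd = psd,
                 sampling_rate_hz = fs, welch_params = params),
            class = "spectrum_estimate")
}

#' Integrate a PSD into band powers with region averaging
#'
#' Band power is the trapezoid integral of the PSD over `[f_low, f_high]`
#' on the Welch grid; because the five bands share their interior edges,
#' per-band trapezoids sum exactly to the full-range integral. Region
#' powers average the constituent channels: C = mean(C1, C2),
#' T = mean(T7, T8), F = Fz, O = Oz, G = mean of all six EEG channels.
#'
#' @param spectrum A `spectrum_estimate` from [welch_psd()].
#' @param bands Band table from [eeg_bands()].
#' @return List of class `band_power_set`: `power` (channels x bands
#'   matrix, µV²) and `region_power` (regions x bands matrix).
#' @export
band_powers <- function(spectrum, bands = eeg_bands()) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  f <- spectrum$frequencies
  if (min(bands$f_low) < min(f) - 1e-9 || max(bands$f_high) > max(f) + 1e-9)
    stop("band outside the frequency grid (grid spans ",
         min(f), "-", max(f), " Hz)")
  trapz_band <- function(p, lo, hi) {
    # trapezoid over [lo, hi] with linear interpolation at the edges
    inside <- which(f > lo & f < hi)
    xs <- c(lo, f[inside], hi)
    ys <- c(stats::approx(f, p, lo)$y, p[inside],
            stats::approx(f, p, hi)$y)
    sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  }
  power <- matrix(0, nrow(spectrum$psd), nrow(bands),
                  dimnames = list(rownames(spectrum$psd), bands$name))
  for (b in seq_len(nrow(bands)))
    power[, b] <- apply(spectrum$psd, 1, trapz_band,
                        lo = bands$f_low[b], hi = bands$f_high[b])
  regions <- region_channels()
  avail <- rownames(power)
  region_power <- t(vapply(regions, function(chs) {
    chs <- intersect(chs, avail)
    if (!length(chs)) return(rep(NA_real_, nrow(bands)))
    colMeans(power[chs, , drop = FALSE])
  }, numeric(nrow(bands))))
  colnames(region_power) <- bands$name
  structure(list(power = power, region_power = region_power,
                 bands = bands), class = "band_power_set")
}

#' Relative band power per region
#'
#' Normalizes each region's band powers by the region's total power over
#' the full analysis range, so each region's fractions sum to exactly 1.
#'
#' @param bp A `band_power_set` from [band_powers()].
#' @return Regions x bands matrix of fractions; a region with zero total
#'   power yields a row of `NA` (flagged for exclusion upstream).
#' @export
relative_power <- function(bp) {
  stopifnot(inherits(bp, "band_power_set"))
  tot <- rowSums(bp$region_power)
  rp <- bp$region_power / tot
  rp[tot <= 0 | !is.finite(tot), ] <- NA_real_
  rp
}

#' Pairwise-derived brain symmetry index
#'
#' Mean over homologous pairs and in-band frequency bins of
#' `|Rt - Lt| / (Rt + Lt)`, where `Rt` and `Lt` are the right- and
#' left-channel PSD values. Ranges from 0 (no asymmetry) to 1 (total
#' asymmetry). Bins where `Rt + Lt = 0` are skipped with the bin count
#' reduced accordingly; if every bin is zero the result is `NA` (feature
#' flagged missing).
#'
#' @param right,left Numeric matrices (pairs x bins) or vectors of PSD
#'   values at matching frequency bins.
#' @return Scalar in `[0, 1]`, or `NA` if undefined.
#' @export
pdbsi <- function(right, left) {
  if (is.vector(right)) right <- matrix(right, 1)
  if (is.vector(left)) left <- matrix(left, 1)
  if (!all(dim(right) == dim(left)))
    stop("right and left PSD matrices must have the same shape")
  if (any(right < 0) || any(left < 0)) stop("PSD values must be nonnegative")
  s <- right + left
  ok <- s > 0
  if (!any(ok)) return(NA_real_)
  mean(abs(right[ok] - left[ok]) / s[ok])
}

#' DAR, DTR and DTABR spectral ratios for one region
#'
#' DAR = delta/alpha, DTR = delta/theta,
#' DTABR = (delta + theta)/(alpha + beta). A zero denominator yields `NA`
#' for that ratio (flagged missing, never infinite).
#'
#' @param region_power Named numeric vector of the five band powers for one
#'   region (names Delta...Gamma).
#' @return Named numeric vector `c(DAR, DTR, DTABR)`.
#' @export
spectral_ratios <- function(region_power) {
  d <- region_power[["Delta"]]; t <- region_power[["Theta"]]
  a <- region_power[["Alpha"]]; b <- region_power[["Beta"]]
  safe_div <- function(num, den) if (!is.na(den) && den > 0) num / den
                                 else NA_real_
  c(DAR = safe_div(d, a), DTR = safe_div(d, t),
    DTABR = safe_div(d + t, a + b))
}

# In-band bin selector for pdBSI: half-open [lo, hi) so per-band features
# never share a bin; broadband uses the full 0.5-44 Hz range.
pdbsi_bins <- function(frequencies, lo, hi) {
  which(frequencies >= lo - 1e-9 & frequencies < hi - 1e-9)
}

#' Build the per-epoch spectral feature table
#'
#' Computes, for every kept epoch, the 49 named features: 25 relative band
#' powers (`RP_<Band>_<Region>` over regions F, C, T, O, G), 10 per-band
#' symmetry indices (`pdBSI_<Band>_<C|T>`), 2 broadband symmetry indices
#' (`pdBSI_C`, `pdBSI_T`) and 12 ratios (`DAR/DTR/DTABR_<Region>` over
#' F, C, T, O), plus the activity `label`. Rows with any undefined
#' mandatory feature are dropped with a logged count.
#'
#' @param epochs An [epoch_set] (only kept epochs are used).
#' @param bands Band table from [eeg_bands()].
#' @param params A [welch_params()].
#' @return A data.frame with the 49 feature columns in fixed order and a
#'   `label` factor column; attribute `dropped` gives the number of rows
#'   dropped for missing features, `epoch_index` the source epoch indices.
#' @export
build_feature_table <- function(epochs, bands = eeg_bands(),
                                params = welch_params()) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep_idx <- which(epochs$kept)
  fnames <- feature_names()
  out <- matrix(NA_real_, length(keep_idx), length(fnames),
                dimnames = list(NULL, fnames))
  labels <- epochs$labels[keep_idx]
  pairs <- homologous_pairs()
  broadband <- c(min(bands$f_low), max(bands$f_high))
  for (r in seq_along(keep_idx)) {
    e <- keep_idx[r]
    eeg <- intersect(epochs$channel_labels, EEG_CHANNELS)
    spec <- welch_psd(epochs$data[eeg, , e], epochs$sampling_rate_hz,
                      params)
    bp <- band_powers(spec, bands)
    rp <- relative_power(bp)
    for (b in bands$name)
      for (reg in c(REGION_NAMES, "G"))
        out[r, paste("RP", b, reg, sep = "_")] <- rp[reg, b]
    for (reg in names(pairs)) {
      rt <- spec$psd[pairs[[reg]][["right"]], ]
      lt <- spec$psd[pairs[[reg]][["left"]], ]
      for (b in seq_len(nrow(bands))) {
        bins <- pdbsi_bins(spec$frequencies, bands$f_low[b],
                           bands$f_high[b])
        out[r, paste("pdBSI", bands$name[b], reg, sep = "_")] <-
          pdbsi(rt[bins], lt[bins])
      }
      bins <- pdbsi_bins(spec$frequencies, broadband[1], broadband[2])
      out[r, paste("pdBSI", reg, sep = "_")] <- pdbsi(rt[bins], lt[bins])
    }
    for (reg in REGION_NAMES) {
      ratios <- spectral_ratios(bp$region_power[reg, ])
      out[r, paste(names(ratios), reg, sep = "_")] <- ratios
    }
  }
  complete <- stats::complete.cases(out)
  n_dropped <- sum(!complete)
  if (n_dropped)
    log_stage("features", sprintf("dropped %d epoch(s) with undefined features",
                                  n_dropped))
  tab <- as.data.frame(out[complete, , drop = FALSE])
  tab$label <- factor(labels[complete], levels = sort(unique(epochs$labels)))
  attr(tab, "dropped") <- n_dropped
  attr(tab, "epoch_index") <- keep_idx[complete]
  attr(tab, "bands") <- bands
  attr(tab, "welch_params") <- params
  tab
}

#' Write a feature table as CSV with a JSON provenance sidecar
#'
#' @param table Feature table from [build_feature_table()].
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  sidecar <- list(bands = attr(table, "bands"),
                  welch_params = unclass(attr(table, "welch_params")),
                  n_rows = nrow(table),
                  dropped = attr(table, "dropped") %||% 0L)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path),
                                       ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
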