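#' Canonical EEG frequency bands
#'
#' The five classical EEG bands used throughout the pipeline. They tile the
#' analysis range 0.5--44 Hz without gaps or overlaps; a shared edge belongs
#' to the upper band (half-open intervals `[f_low, f_high)`), so band powers
#' never double-count a frequency bin.
#'
#' @param names Optional character vector to subset/reorder the bands.
#' @return A data.frame with columns `name`, `f_low`, `f_high` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function(names = NULL) {
  b <- data.frame(
    name   = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    f_low  = c(0.5, 4, 8, 13, 30),
    f_high = c(4, 8, 13, 30, 44),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    idx <- match(names, b$name)
    if (anyNA(idx)) stop("unknown band name(s): ",
                         paste(names[is.na(idx)], collapse = ", "))
    b <- b[idx, , drop = FALSE]
  }
  b
}

#' @keywords internal
BAND_NAMES <- c("Delta", "Theta", "Alpha", "Beta", "Gamma")

#' @keywords internal
REGION_NAMES <- c("F", "C", "T", "O")

# EEG montage used by the study design: frontal midline, central pair,
# temporal pair, occipital midline; EOG/EMG are artifact reference channels.
#' @keywords internal
EEG_CHANNELS <- c("Fz", "C1", "C2", "T7", "T8", "Oz")

#' @keywords internal
REFERENCE_CHANNELS <- c("EOG", "EMG")

#' Channel-to-region mapping
#'
#' Fz maps to the frontal region (F), C1/C2 are averaged into the central
#' region (C), T7/T8 into the temporal region (T), Oz is occipital (O).
#' The synthetic region "G" (global) is the mean over all six EEG channels
#' and is used for relative-power features only.
#'
#' @return Named list: region -> character vector of channel labels.
#' @export
region_channels <- function() {
  list(F = "Fz", C = c("C1", "C2"), T = c("T7", "T8"), O = "Oz",
       G = EEG_CHANNELS)
}

#' Homologous left/right channel pairs
#'
#' Pairs used by the brain symmetry index: (right, left) = (C2, C1) for the
#' central region and (T8, T7) for the temporal region.
#'
#' @return Named list: region -> c(right, left).
#' @export
homologous_pairs <- function() {
  list(C = c(right = "C2", left = "C1"), T = c(right = "T8", left = "T7"))
}

#' Names of the spectral feature columns
#'
#' Fixed, documented column order of the feature table: 25 relative-power
#' features (5 bands x regions F, C, T, O, G), 10 per-band symmetry indices
#' (5 bands x pairs C, T), 2 broadband symmetry indices (C, T), and 12
#' spectral ratios (DAR, DTR, DTABR x regions F, C, T, O) — 49 features.
#'
#' @return Character vector of feature names in table order.
#' @export
feature_names <- function() {
  rp <- as.vector(outer(BAND_NAMES, c(REGION_NAMES, "G"),
                        function(b, r) paste("RP", b, r, sep = "_")))
  pd <- as.vector(outer(BAND_NAMES, c("C", "T"),
                        function(b, r) paste("pdBSI", b, r, sep = "_")))
  pdb <- paste("pdBSI", c("C", "T"), sep = "_")
  ratios <- as.vector(outer(c("DAR", "DTR", "DTABR"), REGION_NAMES, paste,
                            sep = "_"))
  c(rp, pd, pdb, ratios)
}

#' Activity classes recognized by the pipeline
#' @return Character vector of the four activity labels.
#' @export
activity_classes <- function() c("reading", "resting", "walking", "working")
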