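#' Multichannel EEG recording container
#'
#' Holds a channels-by-time sample matrix in microvolts together with its
#' sampling rate and activity annotations. Annotation intervals must be
#' non-overlapping and lie inside the recording.
#'
#' @param samples Numeric matrix, channels x time, with rownames giving the
#'   channel labels (Fz, C1, C2, T7, T8, Oz, optionally EOG/EMG).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param annotations data.frame with columns `start_s`, `end_s`,
#'   `activity` (may have zero rows).
#' @param ground_truth Optional list of simulator ground truth.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sampling_rate_hz, annotations,
                          ground_truth = NULL) {
  if (!is.matrix(samples) || is.null(rownames(samples)))
    stop("`samples` must be a matrix with channel labels as rownames")
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  if (!all(c("start_s", "end_s", "activity") %in% names(annotations)))
    stop("`annotations` needs columns start_s, end_s, activity")
  dur <- ncol(samples) / sampling_rate_hz
  if (nrow(annotations)) {
    a <- annotations[order(annotations$start_s), , drop = FALSE]
    if (any(a$end_s <= a$start_s))
      stop("annotation intervals must have positive length")
    if (any(a$start_s < -1e-9) || any(a$end_s > dur + 1e-9))
      stop("annotation intervals must lie within the recording duration")
    if (nrow(a) > 1 && any(a$start_s[-1] < a$end_s[-nrow(a)] - 1e-9))
      stop("annotation intervals must not overlap")
    annotations <- a
  }
  structure(list(channel_labels = rownames(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 samples = samples,
                 annotations = annotations,
                 ground_truth = ground_truth),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              ncol(x$samples) / x$sampling_rate_hz))
  cat(" channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$activity)
    cat(" annotations:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a recording in the package's CSV dialect
#'
#' Layout: first column `time_s`, one column per channel (microvolts), last
#' column `activity` holding the annotation label covering that sample (or
#' an empty string outside any annotation).
#'
#' @param recording A `raw_recording`.
#' @param path Output/input file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a `raw_recording` (ground truth is not
#'   round-tripped).
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  n <- ncol(recording$samples)
  fs <- recording$sampling_rate_hz
  time_s <- (seq_len(n) - 1) / fs
  activity <- rep("", n)
  for (i in seq_len(nrow(recording$annotations))) {
    a <- recording$annotations[i, ]
    idx <- which(time_s >= a$start_s - 1e-9 & time_s < a$end_s - 1e-9)
    activity[idx] <- a$activity
  }
  df <- data.frame(time_s = time_s, t(recording$samples),
                   activity = activity, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(activity = "character"))
  if (names(df)[1] != "time_s" || names(df)[ncol(df)] != "activity")
    stop("not a recording CSV: expected time_s first and activity last")
  fs <- 1 / stats::median(diff(df$time_s))
  ch <- setdiff(names(df), c("time_s", "activity"))
  samples <- t(as.matrix(df[, ch, drop = FALSE]))
  rownames(samples) <- ch
  act <- df$activity
  ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    activity = character(0))
  if (any(act != "")) {
    r <- rle(act)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != ""
    ann <- data.frame(start_s = df$time_s[starts[keep]],
                      end_s = df$time_s[ends[keep]] + 1 / fs,
                      activity = r$values[keep],
                      stringsAsFactors = FALSE)
  }
  raw_recording(samples, round(fs, 6), ann)
}

#' Read a recording from EDF or CSV by file extension
#' @param path Path ending in `.edf` or `.csv`.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = read_edf(path),
         csv = read_recording_csv(path),
         stop("unsupported recording format: .", ext))
}
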