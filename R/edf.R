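# Minimal EDF+C (continuous, 16-bit) writer and reader: one signal per
# channel, activity annotations stored as standard EDF+ text annotation
# lists (TALs) in an "EDF Annotations" signal. Covers exactly what the
# pipeline needs — whole-second recordings, one data record per second —
# not the full generality of the format.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE,
                                                 scientific = FALSE), width)

#' Write a recording as EDF+ (16-bit, continuous)
#'
#' Each channel becomes one EDF signal in microvolts with a per-channel
#' physical range fitted to its data; annotations become EDF+ TALs. The
#' record duration is 1 s, so the sampling rate must be a whole number and
#' the recording is zero-padded to a whole second if needed.
#'
#' @param recording A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- recording$samples
  n_rec <- as.integer(ceiling(ncol(x) / fs))
  if (ncol(x) < n_rec * fs)
    x <- cbind(x, matrix(0, nrow(x), n_rec * fs - ncol(x)))
  nch <- nrow(x)

  # digital encoding per channel; ranges rounded outward to 2 decimals so
  # the 8-character header fields carry them exactly
  pmin <- floor(apply(x, 1, min) * 100) / 100
  pmax <- ceiling(apply(x, 1, max) * 100) / 100
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- round(sweep(sweep(x, 1, pmin, `-`), 1,
                     (pmax - pmin) / (dmax - dmin), `/`)) + dmin

  # annotation TALs per record: timekeeping plus annotations starting there
  fmt_num <- function(v) format(v, trim = TRUE, scientific = FALSE)
  tals <- vapply(seq_len(n_rec) - 1L, function(r) {
    s <- sprintf("+%s\x14\x14", fmt_num(r))
    ann <- recording$annotations
    if (nrow(ann)) {
      here <- which(ann$start_s >= r & ann$start_s < r + 1)
      for (i in here)
        s <- paste0(s, sprintf("+%s\x15%s\x14%s\x14",
                               fmt_num(ann$start_s[i]),
                               fmt_num(ann$end_s[i] - ann$start_s[i]),
                               ann$activity[i]))
    }
    s
  }, character(1))
  ann_bytes <- 2L * ceiling((max(nchar(tals, type = "bytes")) + 1L) / 2L)
  ann_ns <- ann_bytes %/% 2L

  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate X X X X", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(num_field(header_bytes, 8))
  wr(pad_field("EDF+C", 44))
  wr(num_field(n_rec, 8))
  wr(num_field(1, 8))
  wr(num_field(ns, 4))
  labels <- c(paste("EEG", recording$channel_labels), "EDF Annotations")
  labels[recording$channel_labels %in% REFERENCE_CHANNELS] <-
    recording$channel_labels[recording$channel_labels %in%
                               REFERENCE_CHANNELS]
  for (l in labels) wr(pad_field(l, 16))
  for (i in seq_len(ns)) wr(pad_field("", 80))          # transducer
  for (i in seq_len(ns)) wr(pad_field(if (i <= nch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(num_field(if (i <= nch) pmin[i] else -1, 8))
  for (i in seq_len(ns)) wr(num_field(if (i <= nch) pmax[i] else 1, 8))
  for (i in seq_len(ns)) wr(num_field(dmin, 8))
  for (i in seq_len(ns)) wr(num_field(dmax, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))          # prefiltering
  for (i in seq_len(ns)) wr(num_field(if (i <= nch) fs else ann_ns, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch))
      writeBin(as.integer(dig[i, cols]), con, size = 2, endian = "little")
    tal <- charToRaw(tals[r])
    writeBin(c(tal, raw(ann_bytes - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file written by [write_edf()]
#'
#' Parses the 16-bit signals back to microvolts and EDF+ TALs back into the
#' annotation table. Reference channels are recognized by label.
#'
#' @param path Path to an EDF file.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  rdn <- function(w) as.numeric(trimws(rd(w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rdn(8)                                   # header bytes
  rd(44)
  n_rec <- rdn(8)
  rec_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)             # physical dim
  pmin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  data <- lapply(sig_idx, function(i) numeric(n_rec * spr[i]))
  names(data) <- labels[sig_idx]
  tal_raw <- list()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        tal_raw[[length(tal_raw) + 1L]] <- readBin(con, "raw", 2 * spr[i])
      } else {
        d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        phys <- (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) +
          pmin[i]
        k <- which(sig_idx == i)
        data[[k]][((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
      }
    }
  }
  samples <- do.call(rbind, data)
  rownames(samples) <- sub("^EEG ", "", labels[sig_idx])
  fs <- spr[sig_idx[1]] / rec_dur

  ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    activity = character(0))
  # split the annotation byte stream into TALs at the NUL terminators
  bytes <- do.call(c, tal_raw) %||% raw(0)
  nz <- bytes != as.raw(0)
  runs <- rle(as.integer(nz))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tals <- vapply(which(runs$values == 1L), function(k)
    rawToChar(bytes[starts[k]:ends[k]]), character(1))
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 3) next            # timekeeping-only TAL
    # annotation TALs are concatenated after the timekeeping stamp
    i <- 2L
    while (i + 1L <= length(parts)) {
      od <- strsplit(parts[i], "\x15")[[1]]
      if (length(od) == 2 && !is.na(suppressWarnings(as.numeric(od[1])))) {
        on <- as.numeric(od[1]); du <- as.numeric(od[2])
        ann <- rbind(ann, data.frame(start_s = on, end_s = on + du,
                                     activity = parts[i + 1L],
                                     stringsAsFactors = FALSE))
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  raw_recording(samples, fs, ann)
}
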