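# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings: 256-byte fixed header, 256 bytes per signal
# header, then data records of 16-bit little-endian integers scaled by
# per-signal physical/digital ranges.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, width - 2), format = "fg", width = 1)
  s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Stores one data record per second (all channels must have an integer
#' number of samples per second). Each channel is scaled to the full 16-bit
#' digital range over its own physical range, so round-trip error is bounded
#' by the physical range divided by 65535. Subject, session and KSS are
#' embedded in the recording-identification header field and recovered by
#' [read_edf()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- length(rec$samples[[1]])
  n_rec <- n %/% fs
  if (n_rec * fs != n)
    stop("signal length must be a whole number of 1-s data records")
  ns <- length(rec$samples)

  # symmetric integer physical range: exactly representable in the 8-char
  # ASCII header fields, so no sample is ever clipped
  M <- vapply(rec$samples, function(x) max(1, ceiling(max(abs(x)))), numeric(1))
  phys_min <- -M
  phys_max <- M
  dig_min <- -32768; dig_max <- 32767

  recording_id <- sprintf("Startdate 01-JAN-2000 subject=%s session=%s kss=%s",
                          rec$subject_id, rec$session_id, rec$kss)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                               # version
  wr("X X X X", 80)                        # patient id
  wr(recording_id, 80)                     # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)     # start date/time
  wr(as.character(256 * (1 + ns)), 8)      # header bytes
  wr("", 44)                               # reserved
  wr(as.character(n_rec), 8)               # number of data records
  wr("1", 8)                               # record duration (s)
  wr(as.character(ns), 4)                  # number of signals
  for (ch in rec$channel_names) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)                     # transducer
  for (i in seq_len(ns)) wr("uV", 8)                    # physical dimension
  for (i in seq_len(ns)) wr(edf_num(phys_min[i], 8), 8)
  for (i in seq_len(ns)) wr(edf_num(phys_max[i], 8), 8)
  for (i in seq_len(ns)) wr(as.character(dig_min), 8)
  for (i in seq_len(ns)) wr(as.character(dig_max), 8)
  for (i in seq_len(ns)) wr("", 80)                     # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)        # samples per record
  for (i in seq_len(ns)) wr("", 32)                     # reserved

  # re-read the physical ranges exactly as the reader will parse them, so
  # quantisation is consistent with the truncated ASCII header values
  pmin_hdr <- as.numeric(edf_num(phys_min, 8))
  pmax_hdr <- as.numeric(edf_num(phys_max, 8))
  digital <- lapply(seq_len(ns), function(i) {
    x <- rec$samples[[i]]
    d <- (x - pmin_hdr[i]) / (pmax_hdr[i] - pmin_hdr[i]) *
      (dig_max - dig_min) + dig_min
    as.integer(pmin(pmax(round(d), dig_min), dig_max))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      writeBin(digital[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the fixed-layout EDF header and data records, returning the
#' requested channels in the requested order at their stored physical scale.
#' Subject/session/KSS metadata embedded by [write_edf()] are recovered when
#' present.
#'
#' @param path EDF file path.
#' @param channels Channels to return (default: all, in stored order).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (length(s) == 0) s <- ""   # truncated / malformed file
    trimws(s)
  }
  version <- rd(8)
  rd(80)                                   # patient id
  recording_id <- rd(80)
  rd(8); rd(8)                             # date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (length(ns) != 1 || is.na(ns) || ns < 1)
    stop("not a valid EDF file: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  if (is.null(channels)) channels <- labels
  missing <- setdiff(channels, labels)
  if (length(missing))
    stop("requested channel(s) absent from EDF file: ",
         paste(missing, collapse = ", "))
  sel <- match(channels, labels)
  if (length(unique(spr[sel])) != 1)
    stop("sampling-rate mismatch across requested channels: ",
         paste(unique(spr[sel]), collapse = ", "))
  fs <- spr[sel][1] / rec_dur

  raw <- lapply(sel, function(i) integer(0))
  rec_samples <- sum(spr)
  all_dig <- matrix(readBin(con, integer(), n = rec_samples * n_rec,
                            size = 2, endian = "little"),
                    nrow = rec_samples)
  offsets <- c(0, cumsum(spr))
  samples <- lapply(seq_along(sel), function(j) {
    i <- sel[j]
    rows <- (offsets[i] + 1):offsets[i + 1]
    dig <- as.vector(all_dig[rows, , drop = FALSE])
    (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
  })
  names(samples) <- channels

  meta <- function(key) {
    m <- regmatches(recording_id,
                    regexpr(paste0(key, "=[^ ]+"), recording_id))
    if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
  }
  num_or_na <- function(s) suppressWarnings(as.numeric(s))
  eeg_recording(samples, sampling_rate = fs,
                subject_id = num_or_na(meta("subject")),
                session_id = num_or_na(meta("session")),
                kss = num_or_na(meta("kss")))
}
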