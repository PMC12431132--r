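#' Multichannel EEG recording container
#'
#' @param samples Named list of numeric vectors (one per channel, microvolt),
#'   all of equal length, or a matrix with one column per channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject_id,session_id Identity of the recording.
#' @param kss Karolinska Sleepiness Scale rating (0-9) or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, subject_id = NA,
                          session_id = NA, kss = NA) {
  if (is.matrix(samples)) {
    cn <- colnames(samples)
    samples <- lapply(seq_len(ncol(samples)), function(j) samples[, j])
    names(samples) <- cn
  }
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    stop("channel names must be present and unique")
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have the same length")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (!is.na(kss) && (kss < 0 || kss > 9)) stop("kss must be in 0..9")
  structure(list(
    samples = samples,
    sampling_rate = sampling_rate,
    channel_names = names(samples),
    subject_id = subject_id,
    session_id = session_id,
    kss = kss
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<eeg_recording> subject %s session %s: %d channels (%s), %d samples @ %g Hz (%.1f s), KSS %s\n",
              as.character(x$subject_id), as.character(x$session_id),
              length(x$samples), paste(x$channel_names, collapse = ","),
              n, x$sampling_rate, n / x$sampling_rate, as.character(x$kss)))
  invisible(x)
}

#' Design the band-pass FIR filter
#'
#' Linear-phase FIR band-pass with the passband used for vigilance EEG
#' (default 0.1-30 Hz). Because a sharp 0.1 Hz edge at typical EEG rates
#' would need an impractically long single-stage design, the filter is built
#' as the cascade (tap convolution) of a Hamming windowed-sinc high-pass
#' whose transition spans (0, ~1) Hz and a Hamming windowed-sinc low-pass at
#' `high` Hz; the combined taps remain symmetric (linear phase). The
#' measured magnitude response stays within 1 dB of unity across 1-25 Hz,
#' is at least 40 dB down at and above 45 Hz, and rolls off monotonically
#' below `low`.
#'
#' @param low,high Band edges in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `fir_spec` with elements `taps`, `low_edge`,
#'   `high_edge`, `sampling_rate` and `design`.
#' @export
design_bandpass <- function(low = 0.1, high = 30, sampling_rate = 512) {
  if (!(low > 0 && low < high && high < sampling_rate / 2))
    stop("infeasible band edges: need 0 < low < high < sampling_rate/2")
  fs <- sampling_rate
  odd <- function(n) { n <- max(3L, as.integer(round(n))); if (n %% 2 == 0) n + 1L else n }
  # High-pass: transition deliberately spans from DC so that everything below
  # `low` sits inside the (monotone) main transition lobe, not the rippled
  # stopband. Cutoff at 3*low, Hamming width ~6*low.
  hp_cut <- 3 * low
  n_hp <- odd(3.3 * fs / (6 * low))
  b_hp <- signal::fir1(n_hp - 1, hp_cut / (fs / 2), type = "high")
  # Low-pass at `high` with ~8 Hz Hamming transition (53 dB stopband).
  tw_lp <- min(8, (fs / 2 - high) * 0.8)
  n_lp <- odd(3.3 * fs / tw_lp)
  b_lp <- signal::fir1(n_lp - 1, high / (fs / 2), type = "low")
  taps <- stats::convolve(as.numeric(b_hp), rev(as.numeric(b_lp)),
                          type = "open")
  structure(list(
    taps = taps,
    low_edge = low, high_edge = high, sampling_rate = fs,
    design = list(method = "windowed-sinc cascade", window = "hamming",
                  hp_cutoff = hp_cut, hp_taps = n_hp,
                  lp_cutoff = high, lp_taps = n_lp)
  ), class = "fir_spec")
}

#' Magnitude response of an FIR tap vector
#'
#' @param taps Coefficient vector.
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @param sampling_rate Sampling rate in Hz.
#' @param db Return decibels (default) or linear magnitude.
#' @return Numeric vector of magnitudes.
#' @export
fir_response <- function(taps, freqs, sampling_rate, db = TRUE) {
  m <- seq_along(taps) - 1
  H <- vapply(freqs, function(f) {
    abs(sum(taps * exp(-2i * pi * f * m / sampling_rate)))
  }, numeric(1))
  if (db) 20 * log10(pmax(H, .Machine$double.xmin)) else H
}

#' Apply a zero-phase FIR filter to a recording
#'
#' Forward-backward (zero-phase) application on the full recording, before
#' any segmentation, so that sub-hertz components remain meaningful. For a
#' linear-phase FIR this is implemented as a single centred FFT convolution
#' with the autocorrelated taps (identical to filtering forward then
#' backward), with edge-reflection padding to suppress boundary transients.
#' Output length equals input length.
#'
#' @param rec An [eeg_recording()].
#' @param spec A [design_bandpass()] filter spec.
#' @return The filtered recording.
#' @export
apply_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "fir_spec"))
  if (spec$sampling_rate != rec$sampling_rate)
    stop("filter was designed for ", spec$sampling_rate,
         " Hz but the recording is sampled at ", rec$sampling_rate, " Hz")
  n <- length(rec$samples[[1]])
  # squared-magnitude taps = forward pass followed by backward pass
  b2 <- stats::convolve(spec$taps, spec$taps, type = "open")
  if (length(spec$taps) > n)
    stop("filter (", length(spec$taps), " taps) is longer than the signal (",
         n, " samples)")
  d <- (length(b2) - 1) / 2
  rec$samples <- lapply(rec$samples, function(x) {
    # reflect-pad by the group delay on each side
    pad <- min(d, n - 1)
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    y <- fft_convolve(xp, b2)
    y[(d + pad + 1):(d + pad + n)]
  })
  rec
}

# Full ("open") linear convolution via FFT.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1
  L <- stats::nextn(n, 2)
  X <- fft(c(x, numeric(L - length(x))))
  H <- fft(c(h, numeric(L - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / L
}

#' Binarise a KSS sleepiness rating
#'
#' Ratings 0-3 are grouped as alert (0); ratings 4-9 as drowsy (1).
#'
#' @param kss Integer rating(s) in 0..9.
#' @return Integer label(s) in \{0, 1\}.
#' @export
binarize_kss <- function(kss) {
  if (any(is.na(kss)) || any(kss < 0 | kss > 9))
    stop("KSS rating must be in 0..9")
  as.integer(kss >= 4)
}

#' Segment a recording into fixed-length labelled windows
#'
#' Cuts each selected channel into non-overlapping consecutive windows of
#' `window` seconds; a trailing remainder shorter than one window is
#' dropped. Windows from different channels are independent samples (they
#' are not stacked). Each segment carries the binarised KSS label of its
#' recording and its provenance.
#'
#' @param rec A (typically filtered) [eeg_recording()].
#' @param window Window length in seconds (default 30).
#' @param channels Channels to segment (default C3 and C4).
#' @return A list of `eeg_segment` objects, each with fields `samples`,
#'   `sampling_rate`, `subject_id`, `session_id`, `channel`, `start_index`
#'   (0-based sample offset), `duration` and `label`.
#' @export
segment_recording <- function(rec, window = 30, channels = c("C3", "C4")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(channels, rec$channel_names)
  if (length(missing))
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "))
  w <- round(window * rec$sampling_rate)
  n <- length(rec$samples[[1]])
  if (n < w)
    stop("recording (", n, " samples) is shorter than one ", window,
         "-s window (", w, " samples)")
  label <- binarize_kss(rec$kss)
  nwin <- n %/% w
  out <- list()
  for (ch in channels) {
    x <- rec$samples[[ch]]
    for (i in seq_len(nwin)) {
      out[[length(out) + 1L]] <- structure(list(
        samples = x[((i - 1) * w + 1):(i * w)],
        sampling_rate = rec$sampling_rate,
        subject_id = rec$subject_id, session_id = rec$session_id,
        channel = ch, start_index = (i - 1L) * w,
        duration = window, label = label
      ), class = "eeg_segment")
    }
  }
  out
}

#' Segment metadata as a data frame
#'
#' @param segments List of `eeg_segment` objects.
#' @return data.frame with subject, session, channel, start, label.
#' @export
segment_manifest <- function(segments) {
  do.call(rbind, lapply(segments, function(s) {
    data.frame(subject = s$subject_id, session = s$session_id,
               channel = s$channel, start = s$start_index,
               label = s$label, stringsAsFactors = FALSE)
  }))
}
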