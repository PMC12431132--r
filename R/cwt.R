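# Morlet continuous wavelet transform.
#
# Convention: time is measured in sample units, so for scale l (samples) the
# coefficients are W(l, n) = sum_m x[m] * Conj(psi((m - n) / l)) / sqrt(l),
# the discrete counterpart of the scaled/translated inner-product integral.
# psi(t) = pi^{-1/4} exp(i * omega0 * t) exp(-t^2 / 2) with omega0 = 6, so
# the centre frequency is fc = omega0 / (2*pi) ~ 0.9549 cycles per unit and
# the pseudo-frequency of scale l at sampling rate fs is fc * fs / l.

MORLET_OMEGA0 <- 6
MORLET_FC <- MORLET_OMEGA0 / (2 * pi)
# envelope support: exp(-t^2/2) < 2e-8 beyond |t| = 6
MORLET_SUPPORT <- 6

#' Morlet mother wavelet
#' @param t Time (dimensionless).
#' @param omega0 Centre-frequency parameter (radians per unit time).
#' @return Complex values of the wavelet.
#' @export
morlet <- function(t, omega0 = MORLET_OMEGA0) {
  pi^(-0.25) * exp(1i * omega0 * t) * exp(-t^2 / 2)
}

#' Pseudo-frequency of a wavelet scale
#'
#' `frequency = fc / (scale * sampling interval)`: strictly decreasing in
#' the scale, so doubling the scale halves the frequency.
#'
#' @param scale Positive scale(s) in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param omega0 Morlet centre-frequency parameter.
#' @return Frequency in Hz.
#' @export
scale_to_frequency <- function(scale, sampling_rate, omega0 = MORLET_OMEGA0) {
  if (any(scale <= 0)) stop("scale must be positive")
  (omega0 / (2 * pi)) * sampling_rate / scale
}

#' Inverse of [scale_to_frequency()]
#' @param frequency Frequency in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param omega0 Morlet centre-frequency parameter.
#' @return Scale in samples.
#' @export
frequency_to_scale <- function(frequency, sampling_rate,
                               omega0 = MORLET_OMEGA0) {
  if (any(frequency <= 0)) stop("frequency must be positive")
  (omega0 / (2 * pi)) * sampling_rate / frequency
}

#' Default scalogram scale ladder
#'
#' 64 logarithmically spaced scales spanning pseudo-frequencies 0.5-30 Hz,
#' covering the band-pass filtered EEG band.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param n_scales Number of scales.
#' @param fmin,fmax Frequency span in Hz.
#' @return Increasing numeric vector of scales (samples).
#' @export
default_scales <- function(sampling_rate, n_scales = 64,
                           fmin = 0.5, fmax = 30) {
  freqs <- exp(seq(log(fmax), log(fmin), length.out = n_scales))
  frequency_to_scale(freqs, sampling_rate)
}

# cache of wavelet-kernel FFTs keyed by (fft length, scale ladder)
.cwt_cache <- new.env(parent = emptyenv())

#' Continuous wavelet transform with the Morlet wavelet
#'
#' Computes the scalogram grid of one segment via FFT convolution with
#' sampled, scale-normalised Morlet kernels (identical, to numerical
#' precision, to direct evaluation of the scaled/translated inner-product
#' sum). Kernel FFTs are cached per (segment length, scale ladder).
#'
#' @param segment An `eeg_segment` or a numeric vector.
#' @param scales Positive scales in samples (default [default_scales()] for
#'   the segment's sampling rate).
#' @param sampling_rate Required if `segment` is a bare numeric vector.
#' @return An object of class `scalogram_grid`: complex matrix
#'   `coefficients` (scales x time), `scales`, `pseudo_frequencies`,
#'   `times` (seconds), `wavelet` descriptor and segment provenance.
#' @export
cwt_morlet <- function(segment, scales = NULL, sampling_rate = NULL) {
  if (inherits(segment, "eeg_segment")) {
    x <- segment$samples
    fs <- segment$sampling_rate
    src <- segment[c("subject_id", "session_id", "channel", "start_index",
                     "label")]
  } else {
    x <- as.numeric(segment)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate is required for a bare vector")
    src <- NULL
  }
  n <- length(x)
  if (n == 0) stop("empty segment")
  if (is.null(scales)) scales <- default_scales(fs)
  if (length(scales) == 0) stop("empty scale list")
  if (any(scales <= 0)) stop("scales must be positive")
  half <- ceiling(MORLET_SUPPORT * max(scales))
  if (2 * half + 1 > n)
    stop("largest scale (", max(scales), ") has wavelet support exceeding ",
         "the segment length (", n, " samples)")

  L <- stats::nextn(n + 2 * half, 2)
  key <- paste0(L, ":", n, ":", paste(signif(scales, 10), collapse = ","))
  KF <- .cwt_cache[[key]]
  if (is.null(KF)) {
    KF <- lapply(scales, function(l) {
      h <- ceiling(MORLET_SUPPORT * l)
      m <- (-h):h
      # correlation with Conj(psi((m - n)/l)): because the Morlet wavelet is
      # Hermitian (psi(-t) = Conj(psi(t))) this equals convolution with
      # psi(d/l); laid out so position n lands at output index n
      k <- morlet(m / l) / sqrt(l)
      kern <- complex(L)
      kern[1:(h + 1)] <- k[(h + 1):(2 * h + 1)]   # m = 0..h
      kern[(L - h + 1):L] <- k[1:h]               # m = -h..-1
      fft(kern)
    })
    .cwt_cache[[key]] <- KF
  }
  X <- fft(c(x, numeric(L - n)))
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    w <- fft(X * KF[[i]], inverse = TRUE) / L
    W[i, ] <- w[seq_len(n)]
  }
  structure(list(
    coefficients = W,
    scales = scales,
    pseudo_frequencies = scale_to_frequency(scales, fs),
    times = (seq_len(n) - 1) / fs,
    sampling_rate = fs,
    wavelet = list(family = "morlet", omega0 = MORLET_OMEGA0,
                   center_frequency = MORLET_FC),
    source = src
  ), class = "scalogram_grid")
}

#' Direct (brute-force) evaluation of the wavelet inner product
#'
#' Reference implementation used as an independent oracle: evaluates the
#' scaled/translated inner-product sum term by term. Quadratic in the
#' segment length; intended for short segments only.
#'
#' @inheritParams cwt_morlet
#' @return Complex matrix (scales x time).
#' @export
cwt_morlet_direct <- function(segment, scales, sampling_rate = NULL) {
  x <- if (inherits(segment, "eeg_segment")) segment$samples else
    as.numeric(segment)
  n <- length(x)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  m <- seq_len(n)
  for (i in seq_along(scales)) {
    l <- scales[i]
    for (j in seq_len(n)) {
      W[i, j] <- sum(x * Conj(morlet((m - j) / l))) / sqrt(l)
    }
  }
  W
}
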