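#' Simulation configuration for synthetic vigilance EEG
#'
#' Describes the protocol and spectral content of a simulated cohort:
#' sampling rate, session layout, per-state band amplitudes, 1/f background
#' level, between-subject variability and the KSS ratings attached to each
#' vigilance state. Defaults emulate a 3-session x 10-minute x 512 Hz
#' protocol on five central/midline electrodes, with elevated theta and
#' attenuated alpha in the drowsy state.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param session_duration Session length in seconds.
#' @param n_subjects Number of simulated subjects.
#' @param n_sessions_per_subject Sessions per subject.
#' @param channel_names Electrode names (10-20 system).
#' @param band_powers Named list with elements `alert` and `drowsy`, each a
#'   named numeric vector of mean oscillation amplitudes (microvolt) for the
#'   bands `delta` (0.5-4 Hz), `theta` (4-7 Hz), `alpha` (8-12 Hz) and
#'   `beta` (13-30 Hz).
#' @param pink_noise_level Amplitude of the 1/f background (microvolt).
#' @param subject_effect_sd Relative standard deviation of the log-normal
#'   subject-specific band-gain multipliers (0 disables subject effects).
#' @param kss_map Named integer vector mapping state to a KSS rating.
#' @param state_schedule Character vector of length
#'   `n_sessions_per_subject` giving the vigilance state of each session.
#'   The default (alert, alert, drowsy) mirrors increasing sleep
#'   deprivation across a repeated-session protocol.
#' @param seed Integer seed controlling the whole cohort.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 512,
                       session_duration = 600,
                       n_subjects = 14,
                       n_sessions_per_subject = 3,
                       channel_names = c("Fz", "Cz", "C3", "C4", "Pz"),
                       band_powers = list(
                         alert  = c(delta = 10, theta = 5,  alpha = 20, beta = 8),
                         drowsy = c(delta = 12, theta = 15, alpha = 10, beta = 6)
                       ),
                       pink_noise_level = 10,
                       subject_effect_sd = 0.2,
                       kss_map = c(alert = 3L, drowsy = 7L),
                       state_schedule = NULL,
                       seed = 1L) {
  stopifnot(sampling_rate > 0, session_duration > 0,
            n_subjects >= 1, n_sessions_per_subject >= 1)
  if (is.null(state_schedule)) {
    state_schedule <- rep("alert", n_sessions_per_subject)
    state_schedule[n_sessions_per_subject] <- "drowsy"
  }
  if (length(state_schedule) != n_sessions_per_subject)
    stop("state_schedule must have one entry per session")
  if (!all(state_schedule %in% c("alert", "drowsy")))
    stop("state_schedule entries must be 'alert' or 'drowsy'")
  bands <- eeg_band_edges()
  # Nyquist: must be able to synthesize the highest band edge
  if (sampling_rate <= 2 * max(unlist(bands)))
    stop("sampling_rate must exceed twice the highest synthesized band edge (",
         2 * max(unlist(bands)), " Hz)")
  for (st in c("alert", "drowsy")) {
    bp <- band_powers[[st]]
    if (is.null(bp) || !all(names(bands) %in% names(bp)))
      stop("band_powers$", st, " must name all of: ",
           paste(names(bands), collapse = ", "))
    if (any(bp < 0)) stop("band amplitudes must be non-negative")
  }
  if (pink_noise_level < 0) stop("pink_noise_level must be non-negative")
  if (subject_effect_sd < 0) stop("subject_effect_sd must be non-negative")
  if (band_powers$drowsy[["theta"]] <= band_powers$alert[["theta"]] ||
      band_powers$drowsy[["alpha"]] > band_powers$alert[["alpha"]])
    warning("default separability premise violated: expected drowsy theta > ",
            "alert theta and drowsy alpha <= alert alpha")
  structure(list(
    sampling_rate = sampling_rate,
    session_duration = session_duration,
    n_subjects = as.integer(n_subjects),
    n_sessions_per_subject = as.integer(n_sessions_per_subject),
    channel_names = channel_names,
    band_powers = band_powers,
    pink_noise_level = pink_noise_level,
    subject_effect_sd = subject_effect_sd,
    kss_map = kss_map,
    state_schedule = state_schedule,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Canonical EEG band edges (Hz)
#' @return Named list of c(low, high) band edges.
#' @keywords internal
eeg_band_edges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30))
}

# Deterministic per-entity seed derivation; kept below 2^31-1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(s)
}

# Subject-specific band-gain multipliers, drawn once per subject from the
# cohort seed (log-normal with relative sd subject_effect_sd).
subject_multipliers <- function(config, subject_id) {
  bands <- names(eeg_band_edges())
  if (config$subject_effect_sd == 0)
    return(stats::setNames(rep(1, length(bands)), bands))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1L, subject_id))
  sdlog <- sqrt(log(1 + config$subject_effect_sd^2))
  g <- exp(rnorm(length(bands), mean = -sdlog^2 / 2, sd = sdlog))
  stats::setNames(g, bands)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Band-limited oscillation: sum of sinusoids at frequencies drawn uniformly
# within the band, random phases, slow (< 0.2 Hz) positive amplitude
# modulation. Scaled so its RMS equals `amplitude`.
band_oscillation <- function(n, fs, band, amplitude, n_components = 6) {
  if (amplitude <= 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  freqs <- runif(n_components, band[1], band[2])
  phases <- runif(n_components, 0, 2 * pi)
  x <- numeric(n)
  for (i in seq_len(n_components)) {
    x <- x + sin(2 * pi * freqs[i] * t + phases[i])
  }
  fm <- runif(1, 0.05, 0.2)
  env <- 1 + 0.4 * sin(2 * pi * fm * t + runif(1, 0, 2 * pi))
  x <- x * env
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x * (amplitude / r)
  x
}

# 1/f ("pink") background: spectrally shaped white noise with power
# proportional to 1/f for f >= 0.5 Hz and flat below. RMS = level.
pink_noise <- function(n, fs, level) {
  if (level <= 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to physical frequency
  shape <- 1 / sqrt(pmax(f, 0.5))
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x * (level / sqrt(mean(x^2)))
}

#' Simulate one EEG session
#'
#' Generates a multichannel recording whose per-channel signal is the sum of
#' band-limited oscillations (delta/theta/alpha/beta, amplitudes given by the
#' state's band powers times the subject's band-gain multipliers, with slow
#' random amplitude modulation) plus 1/f background noise. The oscillatory
#' sources are shared across channels (homologous central electrodes are
#' correlated in practice) while the 1/f noise is independent per channel.
#' The result is deterministic given `(config$seed, subject_id, session_id,
#' state)`.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject index (1-based).
#' @param session_id Session index (1-based).
#' @param state `"alert"` or `"drowsy"`.
#'
#' @return An [eeg_recording()] with extra fields `state` (ground truth) and
#'   `subject_gains` (the drawn multipliers), class
#'   `c("synthetic_recording", "eeg_recording")`.
#' @export
simulate_session <- function(config, subject_id, session_id, state) {
  stopifnot(inherits(config, "sim_config"))
  if (!state %in% c("alert", "drowsy"))
    stop("state must be 'alert' or 'drowsy', got: ", state)
  if (subject_id < 1 || subject_id > config$n_subjects)
    stop("subject_id out of range")
  if (session_id < 1 || session_id > config$n_sessions_per_subject)
    stop("session_id out of range")
  fs <- config$sampling_rate
  n <- round(fs * config$session_duration)
  gains <- subject_multipliers(config, subject_id)
  bands <- eeg_band_edges()
  amps <- config$band_powers[[state]]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 2L, subject_id, session_id,
                       if (state == "drowsy") 1L else 0L))

  source_sig <- numeric(n)
  for (b in names(bands)) {
    source_sig <- source_sig +
      band_oscillation(n, fs, bands[[b]], amps[[b]] * gains[[b]])
  }
  samples <- lapply(config$channel_names, function(ch) {
    source_sig + pink_noise(n, fs, config$pink_noise_level)
  })
  names(samples) <- config$channel_names

  rec <- eeg_recording(
    samples = samples, sampling_rate = fs,
    subject_id = subject_id, session_id = session_id,
    kss = config$kss_map[[state]]
  )
  rec$state <- state
  rec$subject_gains <- gains
  class(rec) <- c("synthetic_recording", class(rec))
  rec
}

#' Simulate a full cohort
#'
#' For each subject, generates `n_sessions_per_subject` sessions following
#' the configured state schedule. Subject band-gain multipliers are drawn
#' once per subject. Bit-identical for a fixed configuration.
#'
#' @param config A [sim_config()].
#' @return A list of synthetic recordings (subject-major order).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", config$n_subjects * config$n_sessions_per_subject)
  k <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (sess in seq_len(config$n_sessions_per_subject)) {
      k <- k + 1L
      out[[k]] <- simulate_session(config, subj, sess,
                                   config$state_schedule[sess])
    }
  }
  out
}

#' Export a synthetic cohort as EDF files with a CSV manifest
#'
#' Writes one EDF file per session plus `manifest.csv` (subject, session,
#' state, kss, file) and the simulation configuration as `sim_config.yaml`,
#' so the EDF reader and downstream stages can be exercised end-to-end.
#'
#' @param cohort List of recordings from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @param config Optional [sim_config()] echoed to YAML.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_edf <- function(cohort, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    file <- sprintf("subject%02d-session%d.edf", rec$subject_id,
                    rec$session_id)
    write_edf(rec, file.path(dir, file))
    data.frame(subject = rec$subject_id, session = rec$session_id,
               state = if (is.null(rec$state)) NA_character_ else rec$state,
               kss = rec$kss, file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$band_powers <- lapply(cfg$band_powers, as.list)
    cfg$kss_map <- as.list(cfg$kss_map)
    yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  }
  invisible(manifest)
}
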