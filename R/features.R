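# Phase-resetting features: relative angular speed, normalised amplitude,
# their time means, reset-event detection, and the phase resetting rate.

#' Relative angular speed (RAS)
#'
#' How much faster or slower the instantaneous phase advances than a sine
#' wave at the analysis frequency `f`:
#' `RAS(t) = (phase(t) - phase(t - dt)) / (2 pi f dt) - 1`,
#' with the phase difference corrected by +2pi when
#' `phase(t) - phase(t - dt) - 2 pi f dt < -pi` (the usual wrap) and by
#' -2pi when it exceeds +pi (rare). RAS = 0 means the phase advances
#' exactly at `f`.
#'
#' @param phase Numeric vector of phases in (-pi, pi].
#' @param f Analysis frequency in Hz.
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of length `length(phase) - 1`, aligned to the
#'   later sample of each pair.
#' @export
relative_angular_speed <- function(phase, f, dt) {
  stopifnot(f > 0, dt > 0)
  d <- diff(phase)
  c0 <- 2 * pi * f * dt
  dev <- d - c0
  d[dev < -pi] <- d[dev < -pi] + 2 * pi
  d[dev > pi] <- d[dev > pi] - 2 * pi
  d / c0 - 1
}

#' Normalised amplitude (NA)
#'
#' Wavelet amplitude divided by its grand mean over time and frequency
#' within one channel's decomposition; the grand mean of the result is 1
#' exactly, which makes amplitude comparisons across frequencies and
#' sessions meaningful.
#'
#' @param amplitude Nonnegative frequencies x time matrix for one channel.
#' @return Matrix of the same shape.
#' @export
normalised_amplitude <- function(amplitude) {
  if (any(amplitude < 0)) stop("amplitude must be nonnegative")
  m <- mean(amplitude)
  if (m == 0) stop("degenerate channel: amplitude is identically zero")
  amplitude / m
}

#' Time means of RAS and NA
#'
#' @param ras Frequencies x time matrix (or vector) of RAS values.
#' @param na Frequencies x time matrix (or vector) of normalised
#'   amplitudes.
#' @return List with per-frequency means `mras` and `mna`.
#' @export
mean_features <- function(ras, na) {
  list(mras = unname(rowMeans(rbind(ras))),
       mna = unname(rowMeans(rbind(na))))
}

# Reset detection on one (channel, frequency) series: amplitude strictly
# below both neighbours AND |RAS - MRAS| above threshold. First/last
# samples have no two-sided neighbourhood and cannot be events. `ras[i]`
# pairs samples (i, i+1), so the RAS value at sample t is ras[t - 1].
detect_resets_series <- function(amplitude, ras, mras, threshold) {
  n <- length(amplitude)
  if (n < 3L) return(integer(0L))
  t <- 2L:(n - 1L)
  hit <- amplitude[t] < amplitude[t - 1L] &
    amplitude[t] < amplitude[t + 1L] &
    abs(ras[t - 1L] - mras) > threshold
  t[hit]
}

#' Detect phase-resetting events
#'
#' A reset occurs at sample `t` of the trimmed series when the wavelet
#' amplitude is at a strict local minimum
#' (`A(t) < A(t - dt)` and `A(t) < A(t + dt)`) and the relative angular
#' speed deviates from its time mean by more than the threshold
#' (`|RAS(t) - MRAS| > threshold`). Ties in amplitude produce no event.
#'
#' @param tfr A `"tfr_decomposition"` from [tfr_decompose()].
#' @param threshold Detection threshold on `|RAS - MRAS|`.
#' @return Data frame of events: `channel`, `frequency_hz`, `sample`
#'   (index into the trimmed series), `time_s`, `ras_deviation`.
#' @export
detect_resets <- function(tfr, threshold = 0.05) {
  stopifnot(threshold > 0)
  dt <- tfr$sampling_interval
  freqs <- tfr$grid$frequencies
  out <- vector("list", dim(tfr$phase)[1L] * length(freqs))
  k <- 0L
  for (c in seq_len(dim(tfr$phase)[1L])) {
    for (j in seq_along(freqs)) {
      ras <- relative_angular_speed(tfr$phase[c, j, ], freqs[j], dt)
      mras <- mean(ras)
      amp <- tfr$amplitude[c, j, ]
      ev <- detect_resets_series(amp, ras, mras, threshold)
      k <- k + 1L
      if (length(ev))
        out[[k]] <- data.frame(channel = tfr$channel_labels[c],
                               frequency_hz = freqs[j], sample = ev,
                               time_s = tfr$time_axis[ev],
                               ras_deviation = ras[ev - 1L] - mras,
                               stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(data.frame(channel = character(0L), frequency_hz = numeric(0L),
                      sample = integer(0L), time_s = numeric(0L),
                      ras_deviation = numeric(0L)))
  do.call(rbind, out)
}

#' Phase resetting rate (PRR)
#'
#' Reset events per oscillation cycle:
#' `PRR(channel, f) = count(channel, f) / (duration * f)`, where
#' `duration` is the analysed (trimmed) duration in seconds, so
#' `duration * f` is the number of cycles at `f`.
#'
#' @param events Event data frame from [detect_resets()].
#' @param duration Analysed duration in seconds.
#' @param grid A [frequency_grid()] or numeric frequency vector.
#' @param channel_labels Channels to tabulate (rows of the result).
#' @return Channels x frequencies matrix of PRR values.
#' @export
phase_resetting_rate <- function(events, duration, grid,
                                 channel_labels = epoc_montage) {
  stopifnot(duration > 0)
  freqs <- as_freqs(grid)
  counts <- table(factor(events$channel, levels = channel_labels),
                  factor(events$frequency_hz, levels = freqs))
  prr <- sweep(unclass(counts), 2L, duration * freqs, "/")
  dimnames(prr) <- list(channel_labels, signif(freqs, 6L))
  prr
}

#' Per-session feature extraction (fast path)
#'
#' Runs the whole per-session chain - bandpass, Morlet CWT, edge trim,
#' RAS/NA means, reset detection, PRR - in one compiled pass per channel,
#' without materialising the full phase/amplitude arrays. Numerically
#' identical to composing [tfr_decompose()], [relative_angular_speed()],
#' [normalised_amplitude()], [detect_resets()] and
#' [phase_resetting_rate()].
#'
#' @param session An [eeg_session()].
#' @param config An [analysis_config()].
#' @param fir Optional precomputed FIR coefficients (reused across
#'   sessions).
#' @return Feature table (class `c("prr_features", "data.frame")`) with
#'   one row per (channel, frequency): `participant`, `session`,
#'   `channel`, `frequency_hz`, `mras`, `mna`, `prr`, `n_resets`,
#'   `n_cycles`.
#' @export
session_features <- function(session, config = analysis_config(),
                             fir = NULL) {
  rate <- session$sampling_rate
  freqs <- config$grid$frequencies
  if (any(freqs >= rate / 2)) stop("grid frequency at or above Nyquist")
  if (is.null(fir))
    fir <- fir_bandpass_design(config$bandpass_range[1L],
                               config$bandpass_range[2L], rate)
  sig <- session$signal
  if (anyNA(sig)) stop("session ", session_id(session),
                       " contains gaps; cannot extract features")
  filt <- matrix(0, nrow(sig), ncol(sig))
  for (c in seq_len(nrow(sig)))
    filt[c, ] <- bandpass_filter(sig[c, ], rate = rate, fir = fir)

  trim_k <- round(config$edge_trim * rate)
  res <- session_features_cpp(filt, freqs, rate, config$wavelet_omega0,
                              cwt_nfft(ncol(sig), rate), trim_k,
                              config$ras_threshold)
  nch <- nrow(sig)
  nf <- length(freqs)
  # NA normalisation is per channel: divide time-mean amplitudes by the
  # channel's grand mean over time and frequency.
  mna <- res$amp_mean / rowMeans(res$amp_mean)
  duration <- res$duration
  prr <- sweep(res$n_resets, 2L, duration * freqs, "/")
  df <- data.frame(
    participant = session$participant_id,
    session = session_id(session),
    channel = rep(session$channel_labels, each = nf),
    frequency_hz = rep(freqs, times = nch),
    mras = as.vector(t(res$mras)),
    mna = as.vector(t(mna)),
    prr = as.vector(t(prr)),
    n_resets = as.integer(t(res$n_resets)),
    n_cycles = rep(freqs * duration, times = nch),
    stringsAsFactors = FALSE)
  class(df) <- c("prr_features", "data.frame")
  df
}

#' Extract features for a list of sessions
#'
#' @param sessions List of [eeg_session()] objects (typically the
#'   `included` element of [filter_sessions()]).
#' @param config An [analysis_config()].
#' @return Combined feature table, class `c("prr_features", "data.frame")`.
#' @export
extract_features <- function(sessions, config = analysis_config()) {
  if (length(sessions) == 0L) stop("no sessions supplied")
  rate <- sessions[[1L]]$sampling_rate
  fir <- fir_bandpass_design(config$bandpass_range[1L],
                             config$bandpass_range[2L], rate)
  out <- lapply(sessions, function(s)
    session_features(s, config = config,
                     fir = if (s$sampling_rate == rate) fir else NULL))
  df <- do.call(rbind, out)
  class(df) <- c("prr_features", "data.frame")
  df
}
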