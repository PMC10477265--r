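# Synthetic resting-EEG generator: band-limited oscillators with
# Poisson-like phase-reset events whose rate is linearly coupled to a
# latent standardized mood score, over a 1/f background. The generator
# targets the reset detector's definition (jumps large enough to notch
# the wavelet amplitude and kick the relative angular speed), not a
# biophysical claim.

#' Synthetic-study configuration
#'
#' Defaults emulate the study conditions: 14 sessions of 60 s, 14
#' channels at 128 Hz, oscillators at grid frequencies 4, 8 and 16 Hz
#' with reset/mood coupling of -0.5 events/s per score SD at 8 Hz
#' (negative characteristic frequency) and +0.5 at 16 Hz (positive),
#' integer mood scores from a low-skewed discretised gamma on [0, 50],
#' 1/f background at an oscillation-to-noise amplitude ratio of 3.
#'
#' @param n_sessions Number of sessions in the study.
#' @param n_channels Number of channels (<= 14 uses the standard montage).
#' @param duration Session length in seconds.
#' @param rate Sampling rate in Hz.
#' @param carrier_freqs Oscillator frequencies in Hz (within [2, 32]).
#' @param coupling Named numeric: slope (events/s per score SD) linking
#'   the standardized mood score to the reset rate at that carrier;
#'   positive slope = positive characteristic frequency. Names must be
#'   carrier frequencies.
#' @param base_reset_rate Baseline reset-event rate (events/s) at every
#'   carrier; must keep `base + slope * z >= 0` over |z| <= 3.
#' @param mood_shape,mood_scale Gamma parameters of the integer mood-score
#'   distribution (rounded, truncated to [0, 50]).
#' @param noise_exponent Spectral slope of the 1/f^a background.
#' @param snr Oscillation-to-noise amplitude ratio.
#' @param jump_range Phase-jump magnitude range in radians (drawn uniform,
#'   random sign).
#' @param envelope_sd Log-SD of the slow log-normal amplitude envelope.
#' @param envelope_tau Envelope correlation time in seconds.
#' @param channel_jitter Maximum per-channel event-time jitter in samples
#'   (events are shared across channels).
#' @param amplitude_uV Overall output scale in microvolts.
#' @param seed Integer seed.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_sessions = 14L, n_channels = 14L, duration = 60,
                         rate = 128, carrier_freqs = c(4, 8, 16),
                         coupling = c("8" = -0.5, "16" = 0.5),
                         base_reset_rate = 2.5,
                         mood_shape = 2, mood_scale = 3.5,
                         noise_exponent = 1, snr = 3,
                         jump_range = c(pi / 2, pi),
                         envelope_sd = 0.3, envelope_tau = 1,
                         channel_jitter = 2L, amplitude_uV = 20,
                         seed = 1L) {
  stopifnot(n_sessions >= 1L, n_channels >= 1L, duration > 0, rate > 0,
            base_reset_rate >= 0, snr > 0, envelope_tau > 0,
            length(jump_range) == 2L, jump_range[1L] <= jump_range[2L])
  if (any(carrier_freqs < 2 | carrier_freqs > 32))
    stop("carrier frequencies must lie within [2, 32] Hz")
  if (length(coupling)) {
    if (is.null(names(coupling)))
      stop("coupling must be a named vector (names = carrier frequencies)")
    if (!all(as.numeric(names(coupling)) %in% carrier_freqs))
      stop("coupled frequencies must be carrier frequencies")
    if (base_reset_rate - 3 * max(abs(coupling)) < 0)
      stop("reset rate would go negative within |z| <= 3; raise ",
           "base_reset_rate or lower |coupling|")
  }
  structure(list(n_sessions = as.integer(n_sessions),
                 n_channels = as.integer(n_channels),
                 duration = duration, rate = rate,
                 carrier_freqs = carrier_freqs, coupling = coupling,
                 base_reset_rate = base_reset_rate,
                 mood_shape = mood_shape, mood_scale = mood_scale,
                 noise_exponent = noise_exponent, snr = snr,
                 jump_range = jump_range, envelope_sd = envelope_sd,
                 envelope_tau = envelope_tau,
                 channel_jitter = as.integer(channel_jitter),
                 amplitude_uV = amplitude_uV,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^a background, unit RMS.
pink_noise <- function(n, rate, exponent) {
  w <- rnorm(n)
  W <- fft(w)
  k <- 0:(n - 1L)
  fr <- pmin(k, n - k) * rate / n
  g <- c(0, fr[-1L]^(-exponent / 2))
  x <- Re(fft(W * g, inverse = TRUE) / n)
  x / sd(x)
}

# Bank of slow log-normal amplitude envelopes (mean ~1), one per column.
# The Gaussian-smoothed fields are generated on a coarse grid (16 points
# per correlation time tau) and linearly interpolated to the sample grid;
# at the envelope's bandwidth the interpolation error is negligible.
slow_envelope_bank <- function(n, rate, sd_log, tau, ncol = 1L) {
  coarse <- max(8, 16 / tau)          # coarse sampling rate, Hz
  m <- max(16L, ceiling(n / rate * coarse) + 1L)
  half <- min(max(1L, round(4 * tau * coarse)), m - 1L)
  kern <- dnorm(seq(-half, half) / coarse, sd = tau)
  kern <- kern / sum(kern)
  w <- matrix(rnorm((m + 2L * half) * ncol), ncol = ncol)
  g <- stats::filter(w, kern, method = "convolution", sides = 2L)
  g <- g[(half + 1L):(half + m), , drop = FALSE]
  g <- sweep(g, 2L, apply(g, 2L, sd) / sd_log, "/")
  # linear interpolation of every column onto the sample grid
  pos <- (0:(n - 1L)) / rate * coarse + 1
  lo <- pmin(floor(pos), m - 1L)
  fr <- pos - lo
  gi <- g[lo, , drop = FALSE] * (1 - fr) + g[lo + 1L, , drop = FALSE] * fr
  exp(gi - sd_log^2 / 2)
}

slow_envelope <- function(n, rate, sd_log, tau) {
  as.numeric(slow_envelope_bank(n, rate, sd_log, tau, 1L))
}

#' Generate one synthetic session signal
#'
#' Each channel is a sum over carriers of a narrowband oscillator with a
#' slowly varying log-normal envelope, whose phase jumps by an angle
#' drawn uniform on `jump_range` (random sign) at event times from a
#' Poisson process with rate `base_reset_rate + coupling * mood_z`, plus
#' a 1/f^a background scaled by `snr`. Event times are shared across
#' channels with at most `channel_jitter` samples of per-channel jitter;
#' phase jumps are what the wavelet stage later sees as amplitude notches
#' with large relative-angular-speed excursions. Deterministic given
#' `seed`.
#'
#' @param config A [synth_config()].
#' @param mood_z Standardized mood score of the session.
#' @param seed Optional integer seed (set for reproducibility).
#' @return Channels x samples signal matrix (microvolts) with attribute
#'   `"events"`: a list of planted event-time vectors (seconds), one per
#'   carrier frequency.
#' @export
generate_session_signal <- function(config, mood_z = 0, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$duration * config$rate)
  t <- (0:(n - 1L)) / config$rate
  nch <- config$n_channels
  nf <- length(config$carrier_freqs)
  sig <- matrix(0, nch, n)
  events <- list()
  env <- slow_envelope_bank(n, config$rate, config$envelope_sd,
                            config$envelope_tau, nch * nf)
  for (fi in seq_len(nf)) {
    f <- config$carrier_freqs[fi]
    key <- as.character(f)
    slope <- if (key %in% names(config$coupling)) config$coupling[[key]] else 0
    lambda <- max(0, config$base_reset_rate + slope * mood_z)
    nev <- rpois(1L, lambda * config$duration)
    times <- sort(runif(nev, 0, config$duration))
    angles <- runif(nev, config$jump_range[1L], config$jump_range[2L]) *
      sample(c(-1, 1), nev, replace = TRUE)
    events[[key]] <- times
    samp <- pmin(n, floor(times * config$rate) + 1L)
    for (ch in seq_len(nch)) {
      s_ch <- samp
      if (nev > 0L && config$channel_jitter > 0L)
        s_ch <- pmin(n, pmax(1L, samp +
          sample(-config$channel_jitter:config$channel_jitter, nev,
                 replace = TRUE)))
      delta <- numeric(n)
      for (k in seq_len(nev)) delta[s_ch[k]] <- delta[s_ch[k]] + angles[k]
      jump_phase <- cumsum(delta)
      phi0 <- runif(1L, -pi, pi)
      sig[ch, ] <- sig[ch, ] + env[, (fi - 1L) * nch + ch] *
        cos(2 * pi * f * t + phi0 + jump_phase)
    }
  }
  for (ch in seq_len(nch)) {
    noise <- pink_noise(n, config$rate, config$noise_exponent) / config$snr
    sig[ch, ] <- (sig[ch, ] + noise) * config$amplitude_uV
  }
  attr(sig, "events") <- events
  sig
}

#' Generate a synthetic multi-session study
#'
#' Draws integer mood scores from the configured distribution,
#' standardizes them within the study, builds one session per score with
#' [generate_session_signal()], and returns the sessions together with
#' the planted ground truth for recovery assertions.
#'
#' @param config A [synth_config()] with `n_sessions >= 3`.
#' @param participant Participant id attached to the sessions.
#' @return List: `sessions` (list of [eeg_session()] with `dd_score`
#'   set), `ground_truth` (`coupling`, `scores`, `mood_z`, per-session
#'   planted `events`).
#' @export
generate_study <- function(config, participant = "SIM") {
  stopifnot(inherits(config, "synth_config"), config$n_sessions >= 3L)
  set.seed(config$seed)
  scores <- pmin(50, pmax(0, round(rgamma(config$n_sessions,
                                          shape = config$mood_shape,
                                          scale = config$mood_scale))))
  if (length(unique(scores)) < 2L)
    stop("degenerate mood distribution: all drawn scores equal")
  z <- (scores - mean(scores)) / sd(scores)
  session_seeds <- sample.int(2147483646L, config$n_sessions)
  labels <- if (config$n_channels <= length(epoc_montage))
    epoc_montage[seq_len(config$n_channels)]
  else sprintf("Ch%02d", seq_len(config$n_channels))
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  sessions <- vector("list", config$n_sessions)
  events <- vector("list", config$n_sessions)
  for (i in seq_len(config$n_sessions)) {
    sig <- generate_session_signal(config, z[i], seed = session_seeds[i])
    events[[i]] <- attr(sig, "events")
    attr(sig, "events") <- NULL
    sessions[[i]] <- eeg_session(
      sig, channel_labels = labels, sampling_rate = config$rate,
      participant_id = participant,
      session_time = format(t0 + (i - 1L) * 86400, "%Y-%m-%dT%H:%M:%S"),
      dd_score = scores[i])
  }
  list(sessions = sessions,
       ground_truth = list(coupling = config$coupling, scores = scores,
                           mood_z = z, events = events))
}

#' Write a synthetic study to disk
#'
#' Emits the same per-channel CSV and score-table formats the readers
#' consume (integration-test fixtures), plus the planted ground truth as
#' JSON when jsonlite is available.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(study$sessions, function(s) {
    fname <- paste0(s$participant_id, "_",
                    gsub("[^0-9TA-Za-z]", "", s$session_time), ".csv")
    write_session_csv(s, file.path(dir, fname))
    data.frame(participant_id = s$participant_id,
               session_time = s$session_time, dd_score = s$dd_score,
               medicated = s$medicated, notes = s$notes,
               stringsAsFactors = FALSE)
  })
  write_score_table(do.call(rbind, rows), file.path(dir, "scores.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(study$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
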