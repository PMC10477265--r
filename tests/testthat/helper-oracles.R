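# Independent oracles and fixture builders used across the suite.

# Naive per-sample loop implementation of the reset criterion: amplitude
# strictly below both neighbours and |RAS - MRAS| above threshold.
naive_detect_loop <- function(amplitude, ras, mras, threshold) {
  hits <- integer(0L)
  for (t in 2L:(length(amplitude) - 1L)) {
    if (amplitude[t] < amplitude[t - 1L] &&
        amplitude[t] < amplitude[t + 1L] &&
        abs(ras[t - 1L] - mras) > threshold)
      hits <- c(hits, t)
  }
  hits
}

# Naive branch-by-branch evaluation of the RAS formula.
naive_ras_loop <- function(phase, f, dt) {
  c0 <- 2 * pi * f * dt
  out <- numeric(length(phase) - 1L)
  for (t in 2L:length(phase)) {
    d <- phase[t] - phase[t - 1L]
    if (d - c0 < -pi) d <- d + 2 * pi
    else if (d - c0 > pi) d <- d - 2 * pi
    out[t - 1L] <- d / c0 - 1
  }
  out
}

# Wrap an unbounded phase into (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# A clean sinusoidal session at the given frequencies (one per channel).
sine_session <- function(freqs, duration = 60, rate = 128, dd = 5L,
                         labels = NULL, participant = "P1",
                         time = "2024-01-01T09:00:00") {
  n <- round(duration * rate)
  t <- (0:(n - 1L)) / rate
  sig <- t(vapply(freqs, function(f) sin(2 * pi * f * t), numeric(n)))
  if (is.null(labels)) labels <- epoc_montage[seq_along(freqs)]
  eeg_session(sig, channel_labels = labels, sampling_rate = rate,
              participant_id = participant, session_time = time,
              dd_score = dd)
}

# Small random feature table: n sessions x channels x frequencies, with
# all three features filled from the supplied generator function.
random_feature_table <- function(n_sessions, channels, freqs,
                                 gen = function(k) rnorm(k)) {
  grid <- expand.grid(frequency_hz = freqs, channel = channels,
                      session = sprintf("S@%02d", seq_len(n_sessions)),
                      stringsAsFactors = FALSE)
  df <- data.frame(participant = "S", session = grid$session,
                   channel = grid$channel, frequency_hz = grid$frequency_hz,
                   mras = gen(nrow(grid)), mna = 1 + 0.1 * gen(nrow(grid)),
                   prr = 0.25 + 0.05 * gen(nrow(grid)),
                   n_resets = 0L, n_cycles = 57 * grid$frequency_hz,
                   stringsAsFactors = FALSE)
  class(df) <- c("prr_features", "data.frame")
  df
}

# Byte-level EDF writer built directly from the format definition
# (256-byte fixed header, per-signal header block, int16 little-endian
# data records). Used as an independent oracle for read_edf.
write_edf_fixture <- function(path, signal, labels, rate,
                              physmin = -200, physmax = 200) {
  ns <- nrow(signal)
  n <- ncol(signal)
  record_dur <- 1
  nsamp <- as.integer(rate)
  n_records <- as.integer(n / nsamp)
  stopifnot(n_records * nsamp == n)
  digmin <- -32768; digmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                pad("01.01.24", 8), pad("09.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(n_records, 8),
                pad(record_dur, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  w <- function(vals, width) for (v in vals) writeChar(pad(v, width), con, eos = NULL)
  w(labels, 16); w(rep("", ns), 80); w(rep("uV", ns), 8)
  w(rep(physmin, ns), 8); w(rep(physmax, ns), 8)
  w(rep(digmin, ns), 8); w(rep(digmax, ns), 8)
  w(rep("", ns), 80); w(rep(nsamp, ns), 8); w(rep("", ns), 32)
  gain <- (physmax - physmin) / (digmax - digmin)
  dig <- round((signal - physmin) / gain + digmin)
  stopifnot(all(dig >= digmin & dig <= digmax))
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * nsamp + 1L):(r * nsamp)
    for (i in seq_len(ns))
      writeBin(as.integer(dig[i, idx]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# Scores named by session id, pulled from a list of sessions.
session_scores <- function(sessions) {
  setNames(vapply(sessions, function(s) as.numeric(s$dd_score), numeric(1L)),
           vapply(sessions, session_id, character(1L)))
}
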