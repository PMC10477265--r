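#' Construct one EEG measurement session
#'
#' The atomic analysis unit: a channels x samples signal matrix (microvolts)
#' plus the per-session Depression-Dejection (DD) mood score and metadata.
#' `NA` samples are permitted and interpreted as recording gaps (they
#' terminate the usable segment for quality filtering); infinite values are
#' rejected.
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector of 10-10 position names, one per
#'   signal row.
#' @param sampling_rate Sampling rate in Hz (nominal 128).
#' @param participant_id Participant identifier.
#' @param session_time Session timestamp, ISO-8601 string.
#' @param dd_score Integer DD score in 0..50, or `NA` if the questionnaire
#'   was not answered.
#' @param notes Free-text notes.
#' @param medicated Logical flag; medicated sessions are carried through the
#'   analysis (reported, never excluded).
#' @return An object of class `"eeg_session"`.
#' @export
eeg_session <- function(signal, channel_labels = epoc_montage,
                        sampling_rate = 128, participant_id = "P1",
                        session_time = NA_character_,
                        dd_score = NA_integer_, notes = "",
                        medicated = FALSE) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) != length(channel_labels))
    stop("structural error: signal has ", nrow(signal),
         " channels but ", length(channel_labels), " channel labels")
  if (any(is.infinite(signal)))
    stop("signal contains non-finite (infinite) samples")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (!is.na(dd_score)) {
    dd_score <- as.integer(dd_score)
    if (dd_score < 0L || dd_score > 50L)
      stop("dd_score must lie in [0, 50]")
  } else dd_score <- NA_integer_
  rownames(signal) <- channel_labels
  structure(list(participant_id = as.character(participant_id),
                 session_time = as.character(session_time),
                 signal = signal,
                 channel_labels = as.character(channel_labels),
                 sampling_rate = as.numeric(sampling_rate),
                 dd_score = dd_score,
                 notes = as.character(notes),
                 medicated = isTRUE(medicated)),
            class = "eeg_session")
}

#' Session identifier
#'
#' `participant_id` and `session_time` joined with `"@"`; used to key
#' feature tables and exclusion logs.
#'
#' @param session An [eeg_session()].
#' @return Character scalar.
#' @export
session_id <- function(session) {
  paste(session$participant_id, session$session_time, sep = "@")
}

#' Usable duration of a session
#'
#' Length in seconds of the longest contiguous gap-free segment (columns
#' with any `NA` sample terminate a segment). For gap-free recordings this
#' is simply samples / sampling rate.
#'
#' @param session An [eeg_session()].
#' @return Duration in seconds.
#' @export
session_duration <- function(session) {
  ok <- colSums(is.na(session$signal)) == 0L
  if (all(ok)) return(ncol(session$signal) / session$sampling_rate)
  r <- rle(ok)
  longest <- max(c(0L, r$lengths[r$values]))
  longest / session$sampling_rate
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("EEG session %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              session_id(x), nrow(x$signal), ncol(x$signal),
              x$sampling_rate, session_duration(x)))
  cat(sprintf("  DD score: %s%s\n",
              ifelse(is.na(x$dd_score), "missing", x$dd_score),
              if (x$medicated) " [medicated]" else ""))
  invisible(x)
}
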