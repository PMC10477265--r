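#' Session-level quality filtering
#'
#' Applies the study's inclusion rules before any analysis: a session is
#' excluded iff its usable recording is shorter than
#' `config$min_duration` seconds (default 55 s) or its DD score is
#' missing. Duration is the longest contiguous gap-free segment of the
#' raw recording (see [session_duration()]); the edge trim applied later
#' in the wavelet stage does not count against it. Medicated sessions are
#' never excluded - the flag is carried through for reporting.
#'
#' @param sessions Nonempty list of [eeg_session()] objects.
#' @param config An [analysis_config()].
#' @return List with `included` (untouched sessions passing both rules)
#'   and `exclusion_log`, a data frame with one row per excluded session
#'   (`session`, `duration_s`, `has_score`, `reason`); `reason` is one of
#'   `"short_recording"`, `"missing_score"`, `"both"`.
#' @export
filter_sessions <- function(sessions, config = analysis_config()) {
  if (length(sessions) == 0L) stop("no sessions supplied")
  dur <- vapply(sessions, session_duration, numeric(1L))
  has_score <- !vapply(sessions, function(s) is.na(s$dd_score), logical(1L))
  short <- dur < config$min_duration
  excluded <- short | !has_score
  reason <- character(length(sessions))
  reason[short & !has_score] <- "both"
  reason[short & has_score] <- "short_recording"
  reason[!short & !has_score] <- "missing_score"
  log <- data.frame(
    session = vapply(sessions[excluded], session_id, character(1L)),
    duration_s = dur[excluded],
    has_score = has_score[excluded],
    reason = reason[excluded],
    stringsAsFactors = FALSE)
  list(included = sessions[!excluded], exclusion_log = log)
}

#' Write an exclusion log as TSV
#'
#' @param exclusion_log The `exclusion_log` data frame from
#'   [filter_sessions()].
#' @param path Output path.
#' @export
write_exclusion_log <- function(exclusion_log, path) {
  write.table(exclusion_log, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
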