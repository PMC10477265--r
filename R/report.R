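# Orchestration and reporting: end-to-end study analysis, per-participant
# summary table, correlation-curve plots.

#' Analyse a full study end-to-end
#'
#' Quality-filters the sessions, extracts features, and runs the
#' correlation curves and constrained permutation test per participant.
#' This is the package's single-call pipeline.
#'
#' @param sessions List of [eeg_session()] objects (any number of
#'   participants).
#' @param config An [analysis_config()].
#' @return List of class `"prr_study"`: `exclusion_log`, `features`
#'   (combined feature table), `tests` (named list of
#'   `"prr_swing_test"` per participant), `summary` (one row per
#'   participant: n, max swing, null mean/SD, p).
#' @export
analyze_study <- function(sessions, config = analysis_config()) {
  qc <- filter_sessions(sessions, config)
  if (length(qc$included) == 0L)
    stop("no sessions survive quality filtering")
  features <- extract_features(qc$included, config)
  participants <- unique(features$participant)
  tests <- lapply(participants, function(p) {
    sub <- features[features$participant == p, , drop = FALSE]
    class(sub) <- class(features)
    scores <- vapply(qc$included[vapply(qc$included, function(s)
      s$participant_id == p, logical(1L))],
      function(s) as.numeric(s$dd_score), numeric(1L))
    names(scores) <- vapply(qc$included[vapply(qc$included, function(s)
      s$participant_id == p, logical(1L))], session_id, character(1L))
    constrained_permutation_test(sub, scores, config)
  })
  names(tests) <- participants
  structure(list(exclusion_log = qc$exclusion_log, features = features,
                 tests = tests, summary = participant_summary(tests)),
            class = "prr_study")
}

#' @export
print.prr_study <- function(x, ...) {
  cat(sprintf("Phase-resetting study analysis: %d participant(s), %d excluded session(s)\n",
              length(x$tests), nrow(x$exclusion_log)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-participant summary table
#'
#' One row per participant with the sample size, maximum swing magnitude
#' of the PRR correlation curve, permutation null mean and SD, and the
#' permutation p-value.
#'
#' @param tests List of `"prr_swing_test"` objects.
#' @return Data frame.
#' @export
participant_summary <- function(tests) {
  df <- do.call(rbind, lapply(tests, summary))
  rownames(df) <- NULL
  df
}

#' Plot correlation-versus-frequency curves
#'
#' One feature's CC curve for one channel on a log frequency axis, with
#' two-sided reference significance bounds at alpha = 0.05 (dotted) and
#' 0.01 (solid) from [reference_critical_cc()] (independence/normality
#' reference only).
#'
#' @param x A `"prr_cc"` object.
#' @param channel Channel label (default: first channel).
#' @param feature Feature to plot (default `"prr"`).
#' @param ... Passed to [plot()].
#' @export
plot.prr_cc <- function(x, channel = NULL, feature = "prr", ...) {
  layout <- attr(x, "layout")
  if (is.null(channel)) channel <- layout$channels[1L]
  sub <- x[x$feature == feature & x$channel == channel, , drop = FALSE]
  sub <- sub[order(sub$frequency_hz), , drop = FALSE]
  n <- max(sub$n, na.rm = TRUE)
  plot(sub$frequency_hz, sub$r, log = "x", type = "b", pch = 16,
       ylim = c(-1, 1), xlab = "frequency (Hz)",
       ylab = "correlation with DD score",
       main = sprintf("%s, channel %s (n = %d)", toupper(feature),
                      channel, n), ...)
  abline(h = 0, col = "grey70")
  if (n >= 4) {
    for (a in c(0.05, 0.01)) {
      b <- reference_critical_cc(n, a)
      abline(h = c(-b, b), col = "orange",
             lty = if (a == 0.05) 3L else 1L)
    }
  }
  invisible(x)
}
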