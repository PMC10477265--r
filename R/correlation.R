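# Feature-score correlation curves, reference significance bounds, and
# the cross-frequency PRR difference predictor.

# Layout of a one-participant feature table: session order, channel order
# (montage order when all channels belong to it), ascending frequencies.
feature_layout <- function(features) {
  sessions <- unique(features$session)
  channels <- unique(features$channel)
  if (all(channels %in% epoc_montage))
    channels <- epoc_montage[epoc_montage %in% channels]
  freqs <- sort(unique(features$frequency_hz))
  list(sessions = sessions, channels = channels, freqs = freqs)
}

# Sessions x (channel-major x frequency) matrix of one feature. Column
# c * nfreq + j holds (channel c, frequency j), matching the compiled
# swing statistic's ordering.
feature_matrix <- function(features, value, layout = feature_layout(features)) {
  nf <- length(layout$freqs)
  row <- match(features$session, layout$sessions)
  col <- (match(features$channel, layout$channels) - 1L) * nf +
    match(features$frequency_hz, layout$freqs)
  M <- matrix(NA_real_, length(layout$sessions),
              length(layout$channels) * nf)
  M[cbind(row, col)] <- features[[value]]
  M
}

align_scores <- function(scores, layout, features = NULL) {
  if (is.data.frame(scores)) {
    key <- if (!is.null(scores$session)) scores$session else
      paste(scores$participant_id, scores$session_time, sep = "@")
    scores <- setNames(as.numeric(scores$dd_score), key)
  }
  if (!is.null(names(scores))) {
    s <- as.numeric(scores[layout$sessions])
  } else {
    if (length(scores) != length(layout$sessions))
      stop("unnamed score vector must have one score per session")
    s <- as.numeric(scores)
  }
  s
}

#' Correlation-versus-frequency curves
#'
#' Pearson and Spearman correlation of each feature (MRAS, MNA, PRR) with
#' the DD scores across one participant's sessions, per channel and
#' frequency. Sessions with a missing feature value are dropped pairwise,
#' and the effective sample size is reported per curve point. Spearman
#' uses average ranks for ties (DD scores are small integers).
#'
#' @param features Feature table for one participant
#'   ([extract_features()]).
#' @param scores DD scores: a named vector (names = session ids), an
#'   unnamed vector in session order, or a data frame with `session` (or
#'   `participant_id` + `session_time`) and `dd_score`.
#' @return Data frame of class `c("prr_cc", "data.frame")`: `feature`,
#'   `channel`, `frequency_hz`, `r`, `rs`, `n`.
#' @export
correlation_curves <- function(features, scores) {
  layout <- feature_layout(features)
  if (length(layout$sessions) < 3L)
    stop("need at least 3 sessions to correlate features with scores")
  s <- align_scores(scores, layout)
  if (all(is.na(s)) || sd(s, na.rm = TRUE) == 0)
    stop("DD scores are constant for participant ",
         paste(unique(features$participant), collapse = ","),
         "; correlation undefined")
  out <- vector("list", 3L)
  names(out) <- c("mras", "mna", "prr")
  for (feat in names(out)) {
    M <- feature_matrix(features, feat, layout)
    r <- suppressWarnings(as.numeric(
      cor(s, M, use = "pairwise.complete.obs")))
    rs <- suppressWarnings(as.numeric(
      cor(s, M, use = "pairwise.complete.obs", method = "spearman")))
    nvec <- as.integer(colSums(!is.na(M) & !is.na(s)))
    out[[feat]] <- data.frame(
      feature = feat,
      channel = rep(layout$channels, each = length(layout$freqs)),
      frequency_hz = rep(layout$freqs, times = length(layout$channels)),
      r = r, rs = rs, n = nvec, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "layout") <- layout
  attr(df, "participant") <- unique(features$participant)[1L]
  class(df) <- c("prr_cc", "data.frame")
  df
}

#' Reference critical correlation bound
#'
#' Two-sided critical |r| at significance level `alpha` for `n`
#' independent normal samples, from the exact transform
#' `t = r sqrt((n - 2) / (1 - r^2)) ~ t(n - 2)`. Plotted as a reference
#' line on correlation curves; the independence/normality assumption does
#' not necessarily hold for mood scores, so it is a visual guide only.
#'
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Critical |r| in [0, 1).
#' @examples
#' reference_critical_cc(14, 0.05)  # ~0.532
#' @export
reference_critical_cc <- function(n, alpha = 0.05) {
  if (n < 4) stop("n must be at least 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Cross-frequency PRR difference
#'
#' Per-session difference `PRR(f_pos) - PRR(f_neg)` for one channel -
#' the combined predictor formed from a positive and a negative
#' characteristic frequency, which typically correlates with mood more
#' strongly than either frequency alone.
#'
#' @param features Feature table for one participant.
#' @param f_pos,f_neg Frequencies in Hz; must lie on the analysis grid.
#' @param channel Channel label.
#' @return Named numeric vector, one value per session.
#' @export
feature_difference <- function(features, f_pos, f_neg, channel) {
  layout <- feature_layout(features)
  pick <- function(f) {
    j <- which(abs(layout$freqs - f) <= 1e-6 * f)
    if (!length(j)) {
      near <- layout$freqs[order(abs(layout$freqs - f))][1:2]
      stop(sprintf(
        "frequency %g Hz is not on the analysis grid; nearest grid frequencies: %.4g, %.4g",
        f, near[1L], near[2L]))
    }
    j[1L]
  }
  jp <- pick(f_pos); jn <- pick(f_neg)
  if (!channel %in% layout$channels) stop("unknown channel: ", channel)
  M <- feature_matrix(features, "prr", layout)
  nf <- length(layout$freqs)
  cbase <- (match(channel, layout$channels) - 1L) * nf
  setNames(M[, cbase + jp] - M[, cbase + jn], layout$sessions)
}
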