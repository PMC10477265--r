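# Swing-magnitude statistic on correlation curves and its constrained
# permutation test.

#' Alternating local extrema of a correlation curve
#'
#' Scans a CC-versus-frequency curve for interior local maxima ("positive"
#' peaks) and minima ("negative" peaks). Peak kind is defined by extremum
#' type, not by the sign of the CC, so the statistic remains well defined
#' on arbitrary (e.g. permuted) curves. Interior plateaus of equal values
#' contribute a single peak at the plateau midpoint; curve endpoints are
#' never peaks. Consecutive peaks necessarily alternate in kind.
#' Non-finite values (correlations of constant features) are treated as 0.
#'
#' @param cc Numeric curve values, one per grid frequency (length >= 3).
#' @param frequencies Optional frequency axis (defaults to indices).
#' @return Data frame with `index`, `frequency`, `cc`, `kind`
#'   (`"positive"`/`"negative"`), ordered by frequency; zero rows for
#'   monotone curves.
#' @export
find_alternating_peaks <- function(cc, frequencies = seq_along(cc)) {
  cc <- as.numeric(cc)
  if (length(cc) < 3L) stop("curve must have at least 3 points")
  cc[!is.finite(cc)] <- 0
  r <- rle(cc)
  v <- r$values
  k <- length(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer(0L); val <- numeric(0L); kind <- character(0L)
  if (k >= 3L) {
    for (j in 2L:(k - 1L)) {
      if (v[j] > v[j - 1L] && v[j] > v[j + 1L]) kj <- "positive"
      else if (v[j] < v[j - 1L] && v[j] < v[j + 1L]) kj <- "negative"
      else next
      mid <- (starts[j] + ends[j]) %/% 2L
      idx <- c(idx, mid); val <- c(val, v[j]); kind <- c(kind, kj)
    }
  }
  data.frame(index = idx, frequency = frequencies[idx], cc = val,
             kind = kind, stringsAsFactors = FALSE)
}

#' Swing magnitude of a peak sequence
#'
#' The maximum, over every three consecutive alternating peaks
#' `(p1, p2, p3)`, of `|cc(p2) - (cc(p1) + cc(p3)) / 2|`: the difference
#' between a peak value and the average of its two flanking
#' opposite-kind peaks. Returns 0 when fewer than 3 peaks exist. Since
#' each CC lies in [-1, 1], the swing lies in [0, 2].
#'
#' @param peaks Data frame from [find_alternating_peaks()], or a numeric
#'   vector of peak CC values in frequency order.
#' @return Dimensionless swing magnitude.
#' @examples
#' swing_magnitude(c(-0.69, 0.68, -0.80, 0.65))  # 1.465
#' @export
swing_magnitude <- function(peaks) {
  cc <- if (is.data.frame(peaks)) peaks$cc else as.numeric(peaks)
  m <- length(cc)
  if (m < 3L) return(0)
  max(abs(cc[2L:(m - 1L)] - (cc[1L:(m - 2L)] + cc[3L:m]) / 2))
}

# Swing of a raw curve (peak scan + triple max). R reference for the
# compiled path used inside the permutation loop.
curve_swing <- function(cc, frequencies = seq_along(cc)) {
  swing_magnitude(find_alternating_peaks(cc, frequencies))
}

#' Maximum swing over channels
#'
#' Computes the swing magnitude of one feature's CC curve in every
#' channel and returns the channel attaining the maximum (ties broken by
#' montage order), together with the peak triple that realises it.
#'
#' @param curves A `"prr_cc"` object from [correlation_curves()].
#' @param feature Which feature's curves to use (default `"prr"`).
#' @return List: `best_channel`, `observed_swing`, `triple` (data frame
#'   of the three peaks realising the maximum), `swing_per_channel`
#'   (named vector).
#' @export
max_swing_over_channels <- function(curves, feature = "prr") {
  layout <- attr(curves, "layout")
  sub <- curves[curves$feature == feature, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no curves for feature ", feature)
  channels <- layout$channels
  freqs <- layout$freqs
  swings <- setNames(numeric(length(channels)), channels)
  triples <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    cc <- sub$r[sub$channel == channels[i]][order(
      sub$frequency_hz[sub$channel == channels[i]])]
    p <- find_alternating_peaks(cc, freqs)
    m <- nrow(p)
    if (m >= 3L) {
      d <- abs(p$cc[2L:(m - 1L)] - (p$cc[1L:(m - 2L)] + p$cc[3L:m]) / 2)
      j <- which.max(d)
      swings[i] <- d[j]
      triples[[i]] <- p[j:(j + 2L), c("frequency", "cc", "kind")]
    }
  }
  best <- which.max(swings)  # first maximum = montage-order tie-break
  list(best_channel = channels[best],
       observed_swing = unname(swings[best]),
       triple = triples[[best]],
       swing_per_channel = swings)
}

#' Characteristic frequencies of a correlation curve
#'
#' Frequencies at which the CC curve attains a large positive peak
#' (`cc >= bound`) or a large negative peak (`cc <= -bound`): the
#' individual-specific positive and negative characteristic frequencies.
#'
#' @param cc Curve values per grid frequency.
#' @param frequencies Frequency axis in Hz.
#' @param bound Magnitude threshold for "large" (e.g. a
#'   [reference_critical_cc()] value).
#' @return List with `positive` and `negative` frequency vectors (Hz).
#' @export
characteristic_frequencies <- function(cc, frequencies, bound) {
  p <- find_alternating_peaks(cc, frequencies)
  list(positive = p$frequency[p$kind == "positive" & p$cc >= bound],
       negative = p$frequency[p$kind == "negative" & p$cc <= -bound])
}

#' Constrained permutation test of the CC swing
#'
#' Tests whether the alternation of the PRR correlation-versus-frequency
#' curve (its maximum swing magnitude over all channels) is larger than
#' expected under no feature-score association. Score vectors are
#' shuffled uniformly and a shuffle is *accepted* only if its Pearson
#' correlation with the original scores lies within
#' `[-permutation_cc_bound, permutation_cc_bound]` (default 0.5), so
#' accepted permutations genuinely break the association; sampling
#' continues until `n_permutations` accepted shuffles (duplicates
#' permitted). The p-value is the proportion of accepted permutations
#' whose statistic strictly exceeds the observed one; `p = 0` therefore
#' means "below 1/n_permutations".
#'
#' @param features Feature table for one participant.
#' @param scores DD scores (see [correlation_curves()] for accepted
#'   forms).
#' @param config An [analysis_config()]; uses `n_permutations`,
#'   `permutation_cc_bound`, `random_seed`.
#' @param feature Feature whose curves form the statistic (default
#'   `"prr"`).
#' @return Object of class `"prr_swing_test"`: observed statistic, best
#'   channel and peak triple, per-channel swings, null distribution and
#'   its moments, p-value, characteristic frequencies of the best
#'   channel's curve (bound = [reference_critical_cc()] at alpha 0.05),
#'   sample size, seed.
#' @export
constrained_permutation_test <- function(features, scores,
                                         config = analysis_config(),
                                         feature = "prr") {
  layout <- feature_layout(features)
  n <- length(layout$sessions)
  if (n < 7L) stop("need at least 7 sessions for the permutation test")
  s <- align_scores(scores, layout)
  if (anyNA(s)) stop("missing DD score for a session in the feature table")
  if (sd(s) == 0) stop("constant DD scores; permutation test undefined")

  curves <- correlation_curves(features, s)
  obs <- max_swing_over_channels(curves, feature)

  M <- feature_matrix(features, feature, layout)
  nf <- length(layout$freqs)
  nch <- length(layout$channels)

  set.seed(config$random_seed)
  B <- config$n_permutations
  bound <- config$permutation_cc_bound
  accepted <- matrix(NA_real_, n, B)
  got <- 0L
  proposed <- 0L
  while (got < B) {
    batch <- max(1000L, B - got)
    P <- matrix(0, n, batch)
    for (b in seq_len(batch)) P[, b] <- s[sample.int(n)]
    proposed <- proposed + batch
    cc <- as.numeric(cor(s, P))
    keep <- which(abs(cc) <= bound)
    take <- head(keep, B - got)
    if (length(take)) {
      accepted[, got + seq_along(take)] <- P[, take, drop = FALSE]
      got <- got + length(take)
    }
    if (proposed >= 1e6 && got / proposed < 0.01)
      stop(sprintf(paste0("permutation acceptance rate %.4f%% after %d ",
                          "proposals; scores are too structured for the ",
                          "|CC| <= %g constraint"),
                   100 * got / proposed, proposed, bound))
  }
  Rnull <- suppressWarnings(cor(accepted, M, use = "pairwise.complete.obs"))
  Rnull[!is.finite(Rnull)] <- 0
  null_swings <- swing_max_channels_cpp(Rnull, nf, nch)

  p_value <- sum(null_swings > obs$observed_swing) / B
  cc_best <- curves$r[curves$feature == feature &
                        curves$channel == obs$best_channel]
  cc_best <- cc_best[order(layout$freqs)]
  cf <- characteristic_frequencies(cc_best, layout$freqs,
                                   reference_critical_cc(n, 0.05))
  structure(list(participant = attr(curves, "participant"),
                 n = n,
                 observed_swing = obs$observed_swing,
                 best_channel = obs$best_channel,
                 triple = obs$triple,
                 swing_per_channel = obs$swing_per_channel,
                 null_swings = as.numeric(null_swings),
                 null_mean = mean(null_swings),
                 null_sd = sd(null_swings),
                 p_value = p_value,
                 char_freqs_positive = cf$positive,
                 char_freqs_negative = cf$negative,
                 curves = curves,
                 feature = feature,
                 seed = config$random_seed),
            class = "prr_swing_test")
}

format_p <- function(p, B) {
  if (p == 0) sprintf("< %.3g", 1 / B) else sprintf("%.4g", p)
}

#' @export
print.prr_swing_test <- function(x, ...) {
  B <- length(x$null_swings)
  cat(sprintf("Constrained permutation test of the %s CC swing\n",
              toupper(x$feature)))
  cat(sprintf("  participant %s, n = %d sessions\n", x$participant, x$n))
  cat(sprintf("  max swing over channels: %.3f (channel %s)\n",
              x$observed_swing, x$best_channel))
  cat(sprintf("  null (%d accepted permutations): %.3f +/- %.3f\n",
              B, x$null_mean, x$null_sd))
  cat(sprintf("  p-value: %s\n", format_p(x$p_value, B)))
  if (length(x$char_freqs_positive) || length(x$char_freqs_negative)) {
    cat(sprintf("  characteristic frequencies (Hz): + {%s}  - {%s}\n",
                paste(signif(x$char_freqs_positive, 3L), collapse = ", "),
                paste(signif(x$char_freqs_negative, 3L), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.prr_swing_test <- function(object, ...) {
  data.frame(participant = object$participant, n = object$n,
             max_swing = object$observed_swing,
             best_channel = object$best_channel,
             null_mean = object$null_mean, null_sd = object$null_sd,
             p_value = object$p_value, stringsAsFactors = FALSE)
}

#' @export
plot.prr_swing_test <- function(x, ...) {
  hist(x$null_swings, breaks = 40L, col = "grey85", border = "grey60",
       main = sprintf("Null swing distribution (participant %s)",
                      x$participant),
       xlab = "max swing magnitude over channels",
       xlim = range(c(x$null_swings, x$observed_swing)), ...)
  abline(v = x$observed_swing, col = "red3", lwd = 2)
  legend("topright", bty = "n",
         legend = sprintf("observed = %.3f (p %s)", x$observed_swing,
                          format_p(x$p_value, length(x$null_swings))))
}
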