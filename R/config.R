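#' Logarithmic analysis-frequency grid
#'
#' Builds the dyadic grid of analysis frequencies used for all feature
#' curves: `n` frequencies spaced by a factor `2^(1/voices_per_octave)`,
#' anchored at the top frequency `f_top` and stored ascending. The default
#' is the 40-point, 10-voice grid from ~2.14 to 32 Hz. Alternatively pass
#' explicit `frequencies`; they must still be geometrically spaced at
#' `2^(1/voices_per_octave)` (to within 1e-9 relative).
#'
#' @param f_top Top (anchor) frequency in Hz.
#' @param n Number of grid frequencies.
#' @param voices_per_octave Grid density per octave.
#' @param frequencies Optional explicit ascending frequency vector (Hz).
#' @return An object of class `"frequency_grid"` with elements
#'   `frequencies` (ascending, Hz) and `voices_per_octave`.
#' @examples
#' g <- frequency_grid()
#' range(g$frequencies)  # ~2.14 .. 32 Hz
#' @export
frequency_grid <- function(f_top = 32, n = 40L, voices_per_octave = 10L,
                           frequencies = NULL) {
  voices_per_octave <- as.integer(voices_per_octave)
  if (is.null(frequencies)) {
    stopifnot(f_top > 0, n >= 2L, voices_per_octave >= 1L)
    frequencies <- f_top * 2^(-(rev(seq_len(n)) - 1) / voices_per_octave)
  } else {
    frequencies <- sort(as.numeric(frequencies))
    if (length(frequencies) < 2L) stop("a frequency grid needs at least 2 points")
    step <- 2^(1 / voices_per_octave)
    rat <- frequencies[-1L] / frequencies[-length(frequencies)]
    if (any(abs(rat - step) > 1e-9 * step))
      stop("frequencies must be geometrically spaced at 2^(1/voices_per_octave)")
  }
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  structure(list(frequencies = frequencies,
                 voices_per_octave = voices_per_octave),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("Frequency grid: %d points, %.4g-%.4g Hz, %d voices/octave\n",
              length(f), min(f), max(f), x$voices_per_octave))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline. Defaults mirror the
#' study conditions: 1-40 Hz bandpass, 1.5 s edge trim, reset-detection
#' threshold 0.05 on |RAS - MRAS|, 55 s minimum recording, 10,000
#' accepted permutations constrained to |CC| <= 0.5 with the original
#' scores, Morlet centre frequency omega0 = 6.
#'
#' @param bandpass_range Length-2 numeric, passband in Hz.
#' @param edge_trim Seconds removed from each end after the wavelet
#'   transform (edge-distortion guard).
#' @param ras_threshold Detection threshold on |RAS - MRAS| (dimensionless).
#' @param min_duration Minimum usable recording length in seconds for a
#'   session to enter the analysis.
#' @param n_permutations Number of accepted permutations in the swing test.
#' @param permutation_cc_bound Acceptance bound: a shuffled score vector is
#'   used only if its Pearson correlation with the original scores lies in
#'   `[-bound, bound]`. Must be in (0, 1].
#' @param random_seed Integer seed for the permutation test.
#' @param wavelet_omega0 Morlet centre frequency (dimensionless, rad).
#' @param grid A [frequency_grid()].
#' @return An object of class `"prr_config"`.
#' @export
analysis_config <- function(bandpass_range = c(1, 40), edge_trim = 1.5,
                            ras_threshold = 0.05, min_duration = 55,
                            n_permutations = 10000L,
                            permutation_cc_bound = 0.5,
                            random_seed = 1L, wavelet_omega0 = 6,
                            grid = frequency_grid()) {
  stopifnot(length(bandpass_range) == 2L, all(bandpass_range > 0),
            bandpass_range[1L] < bandpass_range[2L],
            edge_trim >= 0, ras_threshold > 0, min_duration > 0,
            n_permutations >= 1, wavelet_omega0 > 0,
            inherits(grid, "frequency_grid"))
  if (permutation_cc_bound <= 0 || permutation_cc_bound > 1)
    stop("permutation_cc_bound must be in (0, 1]")
  structure(list(bandpass_range = as.numeric(bandpass_range),
                 edge_trim = as.numeric(edge_trim),
                 ras_threshold = as.numeric(ras_threshold),
                 min_duration = as.numeric(min_duration),
                 n_permutations = as.integer(n_permutations),
                 permutation_cc_bound = as.numeric(permutation_cc_bound),
                 random_seed = as.integer(random_seed),
                 wavelet_omega0 = as.numeric(wavelet_omega0),
                 grid = grid),
            class = "prr_config")
}

#' @export
print.prr_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  bandpass:        %.3g-%.3g Hz\n",
              x$bandpass_range[1], x$bandpass_range[2]))
  cat(sprintf("  edge trim:       %.3g s\n", x$edge_trim))
  cat(sprintf("  reset threshold: |RAS - MRAS| > %.3g\n", x$ras_threshold))
  cat(sprintf("  min duration:    %.3g s\n", x$min_duration))
  cat(sprintf("  permutations:    %d accepted, |CC| <= %.3g, seed %d\n",
              x$n_permutations, x$permutation_cc_bound, x$random_seed))
  print(x$grid)
  invisible(x)
}
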