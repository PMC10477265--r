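Package: phaseresetr
Title: Phase-Resetting Rate Analysis of Resting EEG and Mood Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects phase-resetting events in resting-state multichannel
    EEG via an analytic Morlet continuous wavelet decomposition, computes
    the phase resetting rate (PRR), mean relative angular speed (MRAS) and
    mean normalised amplitude (MNA) per channel and frequency, correlates
    these features with per-session depressed-mood scores, and evaluates
    the alternating swing of the correlation-versus-frequency curve with a
    constrained permutation test. Includes readers for EDF and per-channel
    CSV recordings, session-level quality filtering, and a synthetic
    resting-EEG generator with planted reset/mood coupling for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, signal, stats, utils, graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
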