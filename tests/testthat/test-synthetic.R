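# The synthetic resting-EEG generator.

test_that("the generator is deterministic given a seed", {
  sc <- synth_config(n_channels = 2L, duration = 10)
  a <- generate_session_signal(sc, 0.5, seed = 123L)
  b <- generate_session_signal(sc, 0.5, seed = 123L)
  expect_identical(a, b)
  c <- generate_session_signal(sc, 0.5, seed = 124L)
  expect_false(identical(a, c))
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(carrier_freqs = c(1, 8)), "2, 32")
  expect_error(synth_config(coupling = c("9" = 0.5)), "carrier")
  expect_error(synth_config(coupling = c("16" = 1.2), base_reset_rate = 2),
               "negative")
  expect_error(synth_config(coupling = unname(c(0.5))), "named")
})

test_that("a study draws valid scores and attaches them to sessions", {
  sc <- synth_config(n_sessions = 14L, n_channels = 2L, duration = 5)
  study <- generate_study(sc)
  expect_length(study$sessions, 14L)
  dd <- vapply(study$sessions, function(s) s$dd_score, integer(1L))
  expect_true(all(dd >= 0L & dd <= 50L))
  expect_equal(dd, study$ground_truth$scores, ignore_attr = TRUE)
  expect_equal(mean(study$ground_truth$mood_z), 0, tolerance = 1e-12)
  expect_equal(sd(study$ground_truth$mood_z), 1, tolerance = 1e-12)
  expect_equal(study$sessions[[1L]]$channel_labels, epoc_montage[1:2])
  # a degenerate mood distribution is an error
  expect_error(generate_study(synth_config(n_sessions = 5L,
                                           mood_scale = 1e-6)),
               "degenerate")
})

test_that("a clean oscillator without planted events yields no resets", {
  sc <- synth_config(n_channels = 1L, coupling = c(), base_reset_rate = 0,
                     snr = 1e9, envelope_sd = 0)
  sig <- generate_session_signal(sc, 0, seed = 3L)
  s <- eeg_session(sig, channel_labels = "AF3", dd_score = 5L,
                   session_time = "t")
  ft <- session_features(s)
  g <- frequency_grid()$frequencies
  for (f in sc$carrier_freqs) {
    row <- ft[abs(ft$frequency_hz - f) < 1e-9, ]
    expect_lt(row$prr, 0.01)
  }
})

test_that("planted events are recovered by the detection criterion", {
  # event rate low enough that notches rarely collide within the wavelet
  # width, and carriers fast enough to resolve individual events (the
  # Morlet time resolution omega0 / (2 pi f) is ~0.24 s at 4 Hz, so slow
  # carriers genuinely cannot separate nearby resets)
  sc <- synth_config(n_channels = 1L, coupling = c(), base_reset_rate = 0.4)
  sig <- generate_session_signal(sc, 0, seed = 1L)
  events <- attr(sig, "events")
  s <- eeg_session(sig, channel_labels = "AF3", dd_score = 5L,
                   session_time = "t")
  tfr <- tfr_decompose(s)
  ev <- detect_resets(tfr, 0.05)
  hit <- 0L; tot <- 0L
  for (f in c(8, 16)) {
    fg <- frequency_grid()$frequencies
    j <- which.min(abs(fg - f))
    det <- ev$time_s[abs(ev$frequency_hz - fg[j]) < 1e-9]
    for (te in events[[as.character(f)]]) {
      if (te < 1.6 || te > 58.4) next  # trimmed margins
      tot <- tot + 1L
      if (any(abs(det - te) <= 8 / 128)) hit <- hit + 1L
    }
  }
  expect_gt(tot, 30L)
  expect_gte(hit / tot, 0.9)
})

test_that("PRR at an uncoupled frequency is stable across mood scores", {
  sc <- synth_config(n_sessions = 50L, n_channels = 1L, coupling = c(),
                     seed = 7L)
  study <- generate_study(sc)
  ft <- extract_features(study$sessions)
  prr16 <- ft$prr[abs(ft$frequency_hz - 16) < 1e-9]
  expect_lt(abs(cor(prr16, study$ground_truth$scores)), 0.3)
})

test_that("carrier-level PRR grows monotonically with the base reset rate", {
  cc <- vapply(c(0.5, 1.5, 2.5), function(base) {
    sc <- synth_config(n_channels = 1L, coupling = c(),
                       base_reset_rate = base)
    m <- vapply(1:3, function(i) {
      sig <- generate_session_signal(sc, 0, seed = 300L + i)
      s <- eeg_session(sig, channel_labels = "AF3", dd_score = 5L,
                       session_time = paste0("t", i))
      ft <- session_features(s)
      mean(ft$prr[abs(ft$frequency_hz - 16) < 1e-9])
    }, numeric(1L))
    mean(m)
  }, numeric(1L))
  expect_true(all(diff(cc) > 0))
})

test_that("the grid-mean PRR sits at the level seen in resting EEG", {
  sc <- synth_config(n_channels = 4L)
  sig <- generate_session_signal(sc, 0, seed = 9L)
  s <- eeg_session(sig, channel_labels = epoc_montage[1:4], dd_score = 5L,
                   session_time = "t")
  ft <- session_features(s)
  expect_gt(mean(ft$prr), 0.15)
  expect_lt(mean(ft$prr), 0.40)
})

test_that("stronger coupling yields stronger recovered correlations", {
  med <- vapply(c(0, 0.4, 0.8), function(slope) {
    r <- vapply(1:5, function(run) {
      sc <- synth_config(n_sessions = 14L, n_channels = 1L,
                         coupling = if (slope > 0) c("16" = slope) else c(),
                         seed = 400L + run)
      study <- generate_study(sc)
      ft <- extract_features(study$sessions)
      prr16 <- ft$prr[abs(ft$frequency_hz - 16) < 1e-9]
      abs(cor(prr16, study$ground_truth$scores))
    }, numeric(1L))
    median(r)
  }, numeric(1L))
  expect_true(all(diff(med) > 0))
})

test_that("a synthetic study written to disk reads back through the IO layer", {
  sc <- synth_config(n_sessions = 3L, n_channels = 2L, duration = 2)
  study <- generate_study(sc)
  dir <- withr::local_tempdir()
  write_synthetic_study(study, dir)
  scores <- read_score_table(file.path(dir, "scores.tsv"))
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  expect_length(files, 3L)
  back <- read_session(files[1L], scores, channel_labels = epoc_montage[1:2])
  orig <- study$sessions[[1L]]
  expect_equal(back$signal, orig$signal, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$dd_score, orig$dd_score)
})
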