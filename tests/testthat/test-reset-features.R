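# Relative angular speed, normalised amplitude, reset detection, PRR.

test_that("RAS is zero for a pure sinusoid and linear in the advance rate", {
  f <- 10; dt <- 1 / 128
  t <- (0:999) * dt
  ph <- wrap_phase(2 * pi * f * t)
  expect_lt(max(abs(relative_angular_speed(ph, f, dt))), 1e-9)
  ph_fast <- wrap_phase(2 * pi * f * 1.2 * t)
  ras <- relative_angular_speed(ph_fast, f, dt)
  expect_lt(max(abs(ras - 0.2)), 1e-9)
})

test_that("the wrap correction reproduces the worked example", {
  # phi(t-dt) = 3.1, phi(t) = -3.1, f = 10 Hz, dt = 1/128 s: the raw
  # difference -6.2 triggers the +2*pi branch
  ras <- relative_angular_speed(c(3.1, -3.1), 10, 1 / 128)
  exact <- (-3.1 + 2 * pi - 3.1) / (2 * pi * 10 / 128) - 1
  expect_equal(ras, exact, tolerance = 1e-12)
  expect_lt(abs(ras - (-0.8306)), 1e-3)
})

test_that("RAS is invariant under a global phase rotation", {
  set.seed(5)
  f <- 7; dt <- 1 / 128
  ph <- wrap_phase(cumsum(rnorm(500, mean = 2 * pi * f * dt, sd = 0.1)))
  for (rot in c(0.3, -2.9, 1.7)) {
    expect_lt(max(abs(relative_angular_speed(wrap_phase(ph + rot), f, dt) -
                        relative_angular_speed(ph, f, dt))), 1e-12)
  }
})

test_that("exactly one wrap branch applies and recentres the numerator", {
  set.seed(9)
  for (i in 1:200) {
    p1 <- runif(1, -pi, pi)
    p2 <- runif(1, -pi, pi)
    f <- runif(1, 2, 32)
    dt <- 1 / 128
    c0 <- 2 * pi * f * dt
    d <- p2 - p1
    branches <- sum(d - c0 < -pi, d - c0 > pi)
    expect_lte(branches, 1L)
    if (d - c0 < -pi) d <- d + 2 * pi else if (d - c0 > pi) d <- d - 2 * pi
    expect_true(d - c0 > -pi - 1e-12 && d - c0 <= pi + 1e-12)
    # and the vectorised implementation agrees with the naive loop
    expect_equal(relative_angular_speed(c(p1, p2), f, dt),
                 naive_ras_loop(c(p1, p2), f, dt), tolerance = 1e-14)
  }
})

test_that("normalised amplitude has unit grand mean and is scale invariant", {
  expect_true(all(normalised_amplitude(matrix(3.7, 4, 10)) == 1))
  set.seed(2)
  a <- matrix(abs(rnorm(40)), 4)
  expect_equal(normalised_amplitude(2 * a), normalised_amplitude(a))
  expect_equal(mean(normalised_amplitude(a)), 1)
  half <- matrix(c(2, 0), 2, 10)
  expect_true(all(normalised_amplitude(half) %in% c(2, 0)))
  expect_error(normalised_amplitude(matrix(0, 2, 5)), "degenerate")
})

test_that("mean features are plain time means", {
  expect_equal(mean_features(rep(0, 10), rep(1, 10)),
               list(mras = 0, mna = 1))
  expect_equal(mean_features(rep(c(0.1, -0.1), 50), rep(1, 100))$mras, 0)
})

test_that("a pure sinusoid at a grid frequency produces no reset events", {
  s <- sine_session(frequency_grid()$frequencies[18L])
  tfr <- tfr_decompose(s)
  ev <- detect_resets(tfr, 0.05)
  expect_equal(nrow(ev[ev$frequency_hz == frequency_grid()$frequencies[18L], ]),
               0L)
})

test_that("event counts are non-increasing in the threshold", {
  set.seed(21)
  sc <- synth_config(n_channels = 1L, duration = 20)
  sig <- generate_session_signal(sc, 0, seed = 21)
  s <- eeg_session(sig[1L, , drop = FALSE], channel_labels = "AF3",
                   dd_score = 5L, session_time = "t")
  tfr <- tfr_decompose(s)
  counts <- vapply(c(0.01, 0.05, 0.2, 10),
                   function(th) nrow(detect_resets(tfr, th)), numeric(1L))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[4L], 0)  # bounded RAS cannot exceed a huge threshold
})

test_that("vectorised detection equals the naive per-sample loop", {
  set.seed(31)
  grid <- frequency_grid(f_top = 24, n = 8L)
  for (i in 1:20) {
    x <- rnorm(768)
    w <- morlet_cwt(x, grid, 128)
    tr <- trim_edges(w$phase, w$amplitude, 0.5, 128)
    for (j in seq_len(8L)) {
      ras <- relative_angular_speed(tr$phase[j, ], grid$frequencies[j], 1 / 128)
      mras <- mean(ras)
      fast <- phaseresetr:::detect_resets_series(tr$amplitude[j, ], ras,
                                                 mras, 0.05)
      expect_identical(fast, naive_detect_loop(tr$amplitude[j, ], ras,
                                               mras, 0.05))
    }
  }
})

test_that("the compiled fast path matches the composed R pipeline", {
  sc <- synth_config(n_channels = 3L)
  sig <- generate_session_signal(sc, 0.4, seed = 77)
  s <- eeg_session(sig[1:3, ], channel_labels = epoc_montage[1:3],
                   dd_score = 8L, session_time = "t")
  cfg <- analysis_config()
  ft <- session_features(s, cfg)
  tfr <- tfr_decompose(s, cfg)
  ev <- detect_resets(tfr, cfg$ras_threshold)
  duration <- length(tfr$time_axis) / 128
  prr <- phase_resetting_rate(ev, duration, cfg$grid, s$channel_labels)
  for (c in 1:3) {
    rows <- ft[ft$channel == s$channel_labels[c], ]
    expect_equal(rows$prr, unname(prr[c, ]), tolerance = 1e-12)
    ras <- t(vapply(seq_len(40L), function(j)
      relative_angular_speed(tfr$phase[c, j, ], cfg$grid$frequencies[j],
                             1 / 128), numeric(dim(tfr$phase)[3L] - 1L)))
    na <- normalised_amplitude(tfr$amplitude[c, , ])
    mf <- mean_features(ras, na)
    expect_equal(rows$mras, unname(mf$mras), tolerance = 1e-10)
    expect_equal(rows$mna, unname(mf$mna), tolerance = 1e-10)
  }
})

test_that("PRR is events per cycle", {
  ev <- data.frame(channel = rep("AF3", 20L), frequency_hz = 10,
                   sample = 1:20, time_s = 1:20 / 2,
                   ras_deviation = 0.1)
  prr <- phase_resetting_rate(ev, 57, c(5, 10), "AF3")
  expect_equal(unname(prr[1L, "10"]), 20 / 570)
  expect_equal(unname(prr[1L, "5"]), 0)
  # same count at doubled frequency -> half the rate
  ev2 <- ev; ev2$frequency_hz <- 20
  prr2 <- phase_resetting_rate(ev2, 57, c(10, 20), "AF3")
  expect_equal(unname(prr2[1L, "20"]), unname(prr[1L, "10"]) / 2)
})
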