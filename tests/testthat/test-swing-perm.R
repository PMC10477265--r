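# Peak structure, swing magnitude, characteristic frequencies, and the
# constrained permutation test.

test_that("alternating peaks are found with correct kinds and positions", {
  p <- find_alternating_peaks(c(-0.1, 0.5, -0.2, 0.6, -0.3))
  expect_equal(p$index, c(2L, 3L, 4L))
  expect_equal(p$kind, c("positive", "negative", "positive"))
  expect_equal(p$cc, c(0.5, -0.2, 0.6))
  expect_equal(nrow(find_alternating_peaks(1:10 / 10)), 0L)
})

test_that("interior plateaus contribute one peak at their midpoint", {
  p <- find_alternating_peaks(c(0, 1, 1, 0))
  expect_equal(p$index, 2L)
  p2 <- find_alternating_peaks(c(0, 2, 2, 2, 0, -1, 0))
  expect_equal(p2$index, c(3L, 6L))
  expect_equal(p2$kind, c("positive", "negative"))
})

test_that("peak kinds always alternate", {
  set.seed(41)
  for (i in 1:200) {
    cc <- round(rnorm(40), sample(c(1L, 8L), 1L))  # occasional ties
    p <- find_alternating_peaks(cc)
    if (nrow(p) > 1L) expect_true(all(p$kind[-1L] != p$kind[-nrow(p)]))
  }
})

test_that("swing magnitude reproduces the worked example and edge cases", {
  s <- swing_magnitude(c(-0.69, 0.68, -0.80, 0.65))
  expect_gte(s, 1.4645)
  expect_lte(s, 1.4665)
  expect_equal(swing_magnitude(c(1, -1, 1)), 2)
  expect_equal(swing_magnitude(c(0.5, -0.5)), 0)
  expect_equal(swing_magnitude(numeric(0L)), 0)
})

test_that("swing is bounded by 2, negation invariant, and matches the compiled path", {
  set.seed(43)
  for (i in 1:300) {
    cc <- pmin(1, pmax(-1, rnorm(40, sd = 0.5)))
    if (i %% 3L == 0L) cc <- round(cc, 1L)       # force plateaus
    if (i %% 7L == 0L) cc[sample(40L, 3L)] <- NA # constant-feature columns
    r_swing <- phaseresetr:::curve_swing(cc)
    expect_gte(r_swing, 0)
    expect_lte(r_swing, 2)
    expect_equal(r_swing, phaseresetr:::curve_swing(-cc))
    expect_equal(r_swing, phaseresetr:::curve_swing_cpp(cc))
  }
})

test_that("the best channel is selected with montage-order tie-breaks", {
  set.seed(47)
  freqs <- frequency_grid(f_top = 32, n = 10L)$frequencies
  ft <- random_feature_table(10L, c("AF3", "F3"), freqs)
  scores <- setNames(sample(0:30, 10L), unique(ft$session))
  # make F3's PRR flat (uncorrelated constant) and AF3's alternating
  ft$prr[ft$channel == "F3"] <- 0.25
  z <- (scores - mean(scores)) / sd(scores)
  signs <- rep(c(1, -1), length.out = 10L)
  for (j in seq_along(freqs)) {
    sel <- ft$channel == "AF3" & ft$frequency_hz == freqs[j]
    ft$prr[sel] <- 0.25 + signs[j] * 0.05 * z + 0.001 * rnorm(10L)
  }
  cc <- correlation_curves(ft, scores)
  best <- max_swing_over_channels(cc, "prr")
  expect_equal(best$best_channel, "AF3")
  expect_gt(best$observed_swing, 1)
  expect_equal(nrow(best$triple), 3L)
  expect_equal(unname(best$swing_per_channel["F3"]), 0)
})

test_that("characteristic frequencies select large peaks by sign", {
  freqs <- 2^(1:7)
  cc <- c(0.1, 0.75, -0.2, -0.9, 0.3, 0.85, 0.2)
  cf <- characteristic_frequencies(cc, freqs, 0.6)
  expect_equal(cf$positive, c(4, 64))
  expect_equal(cf$negative, 16)
  none <- characteristic_frequencies(c(0.1, 0.2, 0.1, 0.05, 0.15), 1:5, 0.6)
  expect_length(none$positive, 0L)
  expect_length(none$negative, 0L)
})

test_that("geometric-progression peak spacing is recovered on the grid", {
  g <- frequency_grid()
  freqs <- g$frequencies
  targets <- 4 * 2^(0:3 / 2)   # f0 * 2^(k/2)
  idx <- vapply(targets, function(f) which.min(abs(freqs - f)), integer(1L))
  cc <- rep(0, 40L)
  cc[idx] <- c(0.9, -0.9, 0.9, -0.9)
  # smooth slightly so the curve has unambiguous interior extrema
  cc <- as.numeric(stats::filter(c(0, cc, 0), c(0.25, 0.5, 0.25)))[2:41]
  cf <- characteristic_frequencies(cc, freqs, 0.3)
  got <- sort(c(cf$positive, cf$negative))
  expect_length(got, 4L)
  expect_true(all(abs(log2(got / targets)) <= 1.5 / 10))  # within one step
})

test_that("the permutation test is seeded, reproducible, and calibrated on its edge cases", {
  set.seed(51)
  freqs <- frequency_grid(f_top = 32, n = 20L)$frequencies
  n <- 12L
  ft <- random_feature_table(n, c("AF3", "F3", "O1"), freqs)
  scores <- setNames(c(0, 3, 7, 1, 9, 4, 12, 2, 6, 8, 5, 10),
                     unique(ft$session))
  cfg <- analysis_config(n_permutations = 300L, random_seed = 9L)
  t1 <- constrained_permutation_test(ft, scores, cfg)
  t2 <- constrained_permutation_test(ft, scores, cfg)
  expect_identical(t1$null_swings, t2$null_swings)
  expect_identical(t1$p_value, t2$p_value)
  expect_equal(t1$p_value, mean(t1$null_swings > t1$observed_swing))
  expect_equal(length(t1$null_swings), 300L)
  expect_gte(t1$p_value, 0)
  expect_lte(t1$p_value, 1)
})

test_that("a strongly alternating planted signal yields p below every null draw", {
  set.seed(53)
  freqs <- frequency_grid(f_top = 32, n = 20L)$frequencies
  n <- 14L
  z <- rnorm(n)
  ft <- random_feature_table(n, c("AF3", "F3"), freqs)
  signs <- rep(c(1, -1), length.out = 20L)
  for (j in seq_along(freqs)) {
    sel <- ft$channel == "AF3" & ft$frequency_hz == freqs[j]
    ft$prr[sel] <- 0.25 + signs[j] * 0.06 * z + 0.002 * rnorm(n)
  }
  scores <- setNames(z, unique(ft$session))
  cfg <- analysis_config(n_permutations = 300L, random_seed = 3L)
  res <- constrained_permutation_test(ft, scores, cfg)
  expect_equal(res$p_value, 0)
  expect_gt(res$observed_swing, max(res$null_swings))
  expect_equal(res$best_channel, "AF3")
})

test_that("degenerate inputs are rejected with actionable errors", {
  freqs <- c(8, 16, 32)
  ft <- random_feature_table(6L, "AF3", freqs)
  expect_error(constrained_permutation_test(
    ft, setNames(1:6, unique(ft$session))), "at least 7")
  ft2 <- random_feature_table(8L, "AF3", freqs)
  expect_error(constrained_permutation_test(
    ft2, setNames(rep(4, 8L), unique(ft2$session))), "constant")
  # an impossibly tight acceptance bound triggers the acceptance-rate guard
  # (the squared score sum is not divisible by n, so no shuffle can have
  # exactly zero correlation with the original ordering)
  cfg_tight <- analysis_config(n_permutations = 10L,
                               permutation_cc_bound = 1e-9)
  expect_error(constrained_permutation_test(
    ft2, setNames(c(1, 2, 4, 8, 16, 32, 50, 44), unique(ft2$session)),
    cfg_tight), "acceptance rate")
})

test_that("under a true null the test rejects at its nominal rate and p is uniform", {
  set.seed(59)
  freqs <- frequency_grid()$frequencies
  channels <- epoc_montage
  n <- 14L
  B <- 500L
  cfg <- analysis_config(n_permutations = B)
  reps <- 200L
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    ft <- random_feature_table(n, channels, freqs)
    scores <- setNames(sample(0:30, n, replace = TRUE), unique(ft$session))
    while (sd(scores) == 0)
      scores <- setNames(sample(0:30, n, replace = TRUE), unique(ft$session))
    cfg$random_seed <- 1000L + r
    pvals[r] <- constrained_permutation_test(ft, scores, cfg)$p_value
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.075)
  # p roughly uniform: chi-square over 10 bins not rejected at 0.01
  bins <- table(cut(pvals, breaks = seq(0, 1, by = 0.1),
                    include.lowest = TRUE))
  chi <- sum((bins - reps / 10)^2 / (reps / 10))
  expect_lt(chi, qchisq(0.99, df = 9L))
})
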