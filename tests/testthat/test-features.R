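test_that("basic statistics match closed forms", {
  bs <- basic_stats(c(1, -1, 1, -1))
  expect_equal(bs$std, 1)
  expect_equal(bs$range, 2)
  expect_equal(bs$rms, 1)
  const <- basic_stats(rep(3, 7))
  expect_equal(const$std, 0)
  expect_equal(const$range, 0)
  expect_equal(const$rms, 3)
  tt <- seq(0, 1, length.out = 6000)
  expect_equal(basic_stats(sin(2 * pi * tt))$rms, 1 / sqrt(2),
               tolerance = 0.01)
})

test_that("angular jerk matches analytic integrals", {
  fs <- 600
  tt <- seq(0, 1, by = 1 / fs)
  # omega = t^2: second derivative 2, 0.5 * integral(4) = 2
  expect_equal(angular_jerk(tt^2, fs), 2, tolerance = 0.02)
  # linear ramp: zero second derivative
  expect_lt(angular_jerk(5 * tt, fs), 1e-6 * 25)
  # omega = sin(2 pi t): 0.5 * integral((2pi)^4 sin^2) = (2pi)^4 / 4
  expect_equal(angular_jerk(sin(2 * pi * tt), fs), (2 * pi)^4 / 4,
               tolerance = 0.01 * (2 * pi)^4 / 4)
  expect_error(angular_jerk(c(1, 2), fs), "too short")
})

test_that("normalized jerk divides by the slice duration", {
  fs <- 600
  tt <- seq(0, 1, by = 1 / fs)
  expect_equal(normalized_jerk(tt^2, fs), 2, tolerance = 0.02)
  # same curvature over half the duration: integral halves, duration
  # halves -> normalized value unchanged; compare against plain jerk
  half <- tt[tt <= 0.5]
  expect_equal(normalized_jerk(half^2, fs),
               angular_jerk(half^2, fs) / 0.5)
  expect_equal(normalized_jerk(rep(0, 100), fs), 0)
})

test_that("DTW matches a brute-force lattice oracle", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)), 3)
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)),
               dtw_bruteforce(c(0, 0, 0), c(1, 1, 1)))
  set.seed(4)
  for (i in 1:10) {
    a <- round(rnorm(sample(3:5, 1)), 2)
    b <- round(rnorm(sample(3:5, 1)), 2)
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b))
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
})

test_that("peak geometry uses the half-power amplitude convention", {
  fs <- 1000
  tt <- seq(0, 0.4, by = 1 / fs)
  lobe <- 2.5 * sin(pi * tt / 0.4)
  pg <- peak_geometry(lobe, fs)
  expect_equal(pg$peak_height, 2.5, tolerance = 1e-6)
  # sin exceeds 1/sqrt(2) over the middle half of a half-sine
  expect_equal(pg$peak_width_s, 0.2, tolerance = 1 / fs + 1e-9)
  rect <- rep(1, 100)
  expect_equal(peak_geometry(rect, 100)$peak_width_s, 0.99)
  scaled <- peak_geometry(7 * lobe, fs)
  expect_equal(scaled$peak_height, 7 * 2.5, tolerance = 1e-6)
  expect_equal(scaled$peak_width_s, pg$peak_width_s)
  expect_error(peak_geometry(-lobe, fs), "non-positive")
})

test_that("the spectrum is normalized and locates known tones", {
  fs <- 60
  tt <- (0:59) / fs
  sp <- spectrum_type1(sin(2 * pi * 3 * tt), fs)
  expect_equal(sum(sp$power), 1, tolerance = 1e-12)
  expect_lt(abs(sp$freq_hz[which.max(sp$power)] - 3),
            fs / 512 + 1e-9)
  expect_error(spectrum_type1(rep(2, 50), fs), "zero slice")
})

test_that("spectral power is proportional to signal variance", {
  set.seed(5)
  fs <- 60
  x <- rnorm(80)
  xc <- x - mean(x)
  n_fft <- 512
  xp <- c(xc, numeric(n_fft - length(xc)))
  total_power <- sum(Mod(stats::fft(xp))^2) / n_fft
  expect_equal(total_power, sum(xc^2), tolerance = 1e-8)
})

test_that("power spectral entropy follows the stabilized formula", {
  p1 <- c(1, rep(0, 63))
  expect_equal(power_spectral_entropy(p1), -log(1.001),
               tolerance = 1e-12)
  flat <- rep(1 / 64, 64)
  expect_equal(power_spectral_entropy(flat), log(64), tolerance = 0.07)
  expect_gt(power_spectral_entropy(flat), power_spectral_entropy(p1))
  expect_error(power_spectral_entropy(c(0.7, 0.7)), "normalized")
})

test_that("principal harmonic picks the strongest non-DC component", {
  fs <- 60
  tt <- (0:119) / fs
  sp <- spectrum_type1(sin(2 * pi * 2 * tt), fs)
  ph <- principal_harmonic(sp$power, sp$freq_hz)
  df <- sp$freq_hz[2]
  expect_lt(abs(ph$freq_hz - 2), df + 1e-9)
  expect_equal(ph$weighted_peak, ph$amplitude * ph$freq_hz)
  # two tones: the more powerful one wins
  x <- sqrt(0.6) * sin(2 * pi * 1 * tt) + sqrt(0.4) * sin(2 * pi * 4 * tt)
  sp2 <- spectrum_type1(x, fs)
  ph2 <- principal_harmonic(sp2$power, sp2$freq_hz)
  expect_lt(abs(ph2$freq_hz - 1), df + 1e-9)
  # isolated single-bin peak: interpolated width at most two bins
  p <- rep(1e-6, 100); p[11] <- 1; p <- p / sum(p)
  ph3 <- principal_harmonic(p, (0:99) * 0.1)
  expect_lte(ph3$width_hz, 0.2 + 1e-9)
})

test_that("low power frequency separates slow and fast tones", {
  fs <- 60
  tt <- (0:179) / fs
  sp1 <- spectrum_type1(sin(2 * pi * 1 * tt), fs)
  expect_gte(low_power_frequency(sp1$power, sp1$freq_hz), 0.95)
  sp5 <- spectrum_type1(sin(2 * pi * 5 * tt), fs)
  expect_lte(low_power_frequency(sp5$power, sp5$freq_hz), 0.05)
  mix <- sin(2 * pi * 1 * tt) + sin(2 * pi * 5 * tt)
  spm <- spectrum_type1(mix, fs)
  expect_equal(low_power_frequency(spm$power, spm$freq_hz), 0.5,
               tolerance = 0.05)
})

test_that("per-step vectors carry all 16 features and drop boundary steps", {
  f <- small_features()
  expect_true(all(fog_feature_names() %in% names(f)))
  expect_equal(sum(vapply(f[fog_feature_names()], anyNA, NA)), 0)
  # step < stride holds for regular alternating gait; steps resuming
  # after a FOG episode can break alternation, so the bound is a
  # large-majority property on an episode-rich cohort
  expect_gt(mean(f$stride_time_s > f$step_time_s), 0.85)
})

test_that("features are invariant to pre-normalization scaling", {
  p <- gait_profile(noise_sd = 0.02)
  tr <- generate_trial(p, duration_s = 25, seed = 13, sync_offset_s = 0.3)
  scaled <- tr
  scaled$left$samples <- 4.2 * tr$left$samples
  scaled$right$samples <- 4.2 * tr$right$samples
  a <- extract_trial_features(tr)
  b <- extract_trial_features(scaled)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("steady gait yields repeatable strides and low-frequency power", {
  p <- gait_profile(cadence_hz = 1, noise_sd = 0)
  tr <- generate_trial(p, duration_s = 27, seed = 21, sync_offset_s = 0.4)
  f <- extract_trial_features(tr)
  expect_lt(max(f$stride_similarity), 0.05 * max(f$rms) * 60)
  expect_gt(mean(f$low_power_frequency), 0.5)
  expect_equal(mean(f$step_time_s), mean(f$stride_time_s) / 2,
               tolerance = 1 / 60)
})

test_that("pre-FOG steps show the degradation direction", {
  f <- small_features()
  dat <- small_prediction_data()
  pre <- dat$label == 1
  expect_gt(mean(dat$peak_height[!pre]), mean(dat$peak_height[pre]))
  expect_gt(mean(dat$stride_time_s[!pre]), mean(dat$stride_time_s[pre]))
})
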