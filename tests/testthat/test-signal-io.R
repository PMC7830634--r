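test_that("mean-range normalization matches the closed form", {
  tr <- raw_trace(c(1, 2, 3), 60, "left")
  expect_equal(normalize_signal(tr)$samples, c(-0.5, 0, 0.5))
  tr2 <- raw_trace(c(0, 10), 60, "left")
  expect_equal(normalize_signal(tr2)$samples, c(-0.5, 0.5))
})

test_that("normalization rejects constant signals and is idempotent", {
  expect_error(normalize_signal(raw_trace(rep(5, 10), 60, "left")),
               "zero-range")
  set.seed(1)
  tr <- raw_trace(rnorm(500), 60, "left")
  once <- normalize_signal(tr)
  twice <- normalize_signal(once)
  expect_lt(max(abs(once$samples - twice$samples)), 1e-9)
  expect_lt(abs(mean(once$samples)), 1e-9)
  expect_equal(max(once$samples) - min(once$samples), 1, tolerance = 1e-9)
})

test_that("stand-up synchronization recovers an injected offset", {
  p <- gait_profile(noise_sd = 0.02)
  tr <- generate_trial(p, duration_s = 25, seed = 11, sync_offset_s = 0.5)
  s <- synchronize_legs(normalize_signal(tr$left),
                        normalize_signal(tr$right))
  expect_lt(abs(s$estimated_delay_s - 0.5), 1 / 60 + 1e-9)
  expect_equal(length(s$left$samples), length(s$right$samples))
})

test_that("synchronization is antisymmetric and handles zero offset", {
  p <- gait_profile(noise_sd = 0.02)
  tr <- generate_trial(p, duration_s = 25, seed = 12, sync_offset_s = 0.4)
  nl <- normalize_signal(tr$left); nr <- normalize_signal(tr$right)
  ab <- synchronize_legs(nl, nr)
  ba <- synchronize_legs(nr, nl)
  expect_equal(ab$estimated_delay_s, -ba$estimated_delay_s)
  same <- synchronize_legs(nl, nl)
  expect_equal(same$estimated_delay_s, 0)
})

test_that("flat traces raise a no-stand-up-peak error", {
  set.seed(2)
  flat <- raw_trace(rnorm(600, 0, 1), 60, "left")
  expect_error(synchronize_legs(flat, flat), "stand-up peak")
})

test_that("trial CSV round-trip preserves samples and annotations", {
  dir <- withr::local_tempdir()
  p <- gait_profile(noise_sd = 0.02)
  ep <- list(fog_episode(15, 3, at_gait_initiation = FALSE))
  tr <- generate_trial(p, ep, duration_s = 25, seed = 4,
                       sync_offset_s = 0.3, subject_id = "S9",
                       condition = "off", trial_id = "S9_off_1")
  paths <- write_trial_csv(tr, dir)
  back <- read_trial_csv(paths$left, paths$right, paths$annotations)
  # samples are written with 6 decimals; the round-trip is exact at that
  # precision
  expect_equal(back$left$samples, round(tr$left$samples, 6))
  expect_equal(back$right$samples, round(tr$right$samples, 6))
  expect_equal(back$subject_id, "S9")
  expect_equal(back$condition, "off")
  expect_equal(nrow(back$annotations), 1)
  expect_equal(back$annotations$start_s, 15)
  expect_equal(nrow(back$gap_log), 0)
})

test_that("time-column gaps are logged, not repaired", {
  dir <- withr::local_tempdir()
  tt <- (0:599) / 60
  tt[301:600] <- tt[301:600] + 3 / 60      # 3-sample dropout
  df <- data.frame(time_s = tt, omega_x = sin(tt))
  path <- file.path(dir, "gap.csv")
  write.csv(df, path, row.names = FALSE)
  out <- fogpredict:::read_leg_csv(path, "left", 60)
  expect_equal(nrow(out$gaps), 1)
  expect_equal(out$gaps$after_row, 300)
  expect_length(out$trace$samples, 600)
})

test_that("malformed trial files produce named errors", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  write.csv(data.frame(time_s = 1:5, wrong = 1:5), path,
            row.names = FALSE)
  expect_error(fogpredict:::read_leg_csv(path, "left", 60), "omega_x")
  path2 <- file.path(dir, "nonmono.csv")
  write.csv(data.frame(time_s = c(0, 2, 1) / 60, omega_x = 1:3), path2,
            row.names = FALSE)
  expect_error(fogpredict:::read_leg_csv(path2, "left", 60),
               "non-monotonic")
  path3 <- file.path(dir, "empty.csv")
  write.csv(data.frame(time_s = numeric(0), omega_x = numeric(0)), path3,
            row.names = FALSE)
  expect_error(fogpredict:::read_leg_csv(path3, "left", 60), "empty")
})

test_that("cohort write/read round-trip preserves the manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 2, trials_per_subject = 1,
                       trial_duration_s = 30)
  co <- generate_cohort(cfg, seed = 6)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_setequal(back$manifest$trial_id, co$manifest$trial_id)
  tid <- co$manifest$trial_id[1]
  expect_equal(back$trials[[tid]]$left$samples,
               round(co$trials[[tid]]$left$samples, 6))
  expect_equal(as.data.frame(back$trials[[tid]]$annotations[, 1:2]),
               as.data.frame(co$trials[[tid]]$annotations[, 1:2]),
               tolerance = 1e-9)
})
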