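test_that("zero duration yields an empty timeline", {
  tl <- simulate_phase_timeline(quick_config(duration = 0))
  expect_s3_class(tl, "gait_timeline")
  expect_equal(nrow(tl), 0)
})

test_that("inconsistent gait fractions are rejected", {
  expect_error(quick_config(stance_fraction = 0.3,
                            double_support_fraction = 0.2),
               "inconsistent")
  expect_error(quick_config(sensor_rate = 0), "sensor_rate")
  expect_error(quick_config(jump_times = c(2, 30), walk_onset = 5),
               "precede")
})

test_that("double-support occupancy matches twice the configured fraction", {
  cfg <- gait_sim_config(duration = 300, stance_fraction = 0.6,
                         double_support_fraction = 0.1,
                         nc_margin_fraction = 0, jump_times = numeric(0),
                         walk_onset = 0, rng_seed = 2)
  tl <- simulate_phase_timeline(cfg)
  frac <- mean(tl$phase == "RSTLST")
  expect_equal(frac, 0.2, tolerance = 0.05) # 1% absolute on a 20% share
  expect_lt(abs(frac - 0.2), 0.01)
})

test_that("single-support phases never transition into each other directly", {
  for (seed in 1:3) {
    tl <- simulate_phase_timeline(quick_config(duration = 60,
                                               rng_seed = seed))
    ph <- as.character(tl$phase)
    runs <- rle(ph)$values
    pairs <- cbind(head(runs, -1), tail(runs, -1))
    swap <- (pairs[, 1] == "RSWLST" & pairs[, 2] == "RSTLSW") |
      (pairs[, 1] == "RSTLSW" & pairs[, 2] == "RSWLST")
    expect_false(any(swap))
  }
})

test_that("NC samples appear only in the turnaround windows", {
  tl <- simulate_phase_timeline(quick_config(duration = 60))
  nc <- as.character(tl$phase) == "NC"
  expect_true(all(tl$body_x[nc] < 0.15 | tl$body_x[nc] > 0.85))
  expect_true(all(tl$body_x[!nc] >= 0.15 & tl$body_x[!nc] <= 0.85))
})

test_that("identical config and seed reproduce all three streams exactly", {
  cfg <- quick_config(duration = 15, rng_seed = 99)
  a <- simulate_participant(cfg)
  b <- simulate_participant(cfg)
  expect_identical(a$timeline, b$timeline)
  expect_identical(a$track, b$track)
  expect_identical(a$recording, b$recording)
})

test_that("an all-stance noiseless trial gives constant landmarks", {
  cfg <- gait_sim_config(duration = 4, walk_onset = 10,
                         jump_times = numeric(0), keypoint_noise_sd = 0,
                         noise_sd = 0, rng_seed = 1)
  tl <- simulate_phase_timeline(cfg)
  expect_true(all(tl$phase == "RSTLST"))
  trk <- simulate_keypoints(tl, cfg)
  spread <- tapply(trk$x, trk$landmark, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("foot displacement during walking is consistent with the pace", {
  cfg <- gait_sim_config(duration = 60, keypoint_noise_sd = 0, rng_seed = 3)
  tl <- simulate_phase_timeline(cfg)
  trk <- simulate_keypoints(tl, cfg)
  heel <- trk[trk$landmark == "right_heel", ]
  p2m <- default_pixel_to_meter(cfg$path_length)

  # average foot speed over whole strides, excluding the turnaround dwells,
  # equals the walking speed
  mid <- heel$time > 10 & heel$time < 50
  travel <- sum(abs(diff(heel$x[mid]))) * p2m
  moving_frac <- mean(abs(diff(tl$body_s[tl$time > 10 & tl$time < 50])) > 0)
  avg_speed <- travel / (diff(range(heel$time[mid])) * moving_frac)
  expect_equal(avg_speed, cfg$walking_speed, tolerance = 0.15)

  # stance-foot speed is below swing-foot speed
  sp <- estimate_landmark_speed(trk, "right_heel",
                                labeler_config(smoothing_window = 1))
  frames <- sort(unique(trk$time))
  ph <- as.character(tl$cycle_phase)[findInterval(frames, tl$time)]
  expect_lt(median(sp[ph == "RSTLST"]), median(sp[ph == "RSWLST"]))
})

test_that("jumps displace both heels at the configured times", {
  cfg <- gait_sim_config(duration = 8, jump_times = 2, walk_onset = 6,
                         keypoint_noise_sd = 0, rng_seed = 1)
  tl <- simulate_phase_timeline(cfg)
  trk <- simulate_keypoints(tl, cfg)
  for (lm in c("left_heel", "right_heel")) {
    h <- trk[trk$landmark == lm, ]
    peak_t <- h$time[which.min(h$y)] # lift = decreasing y
    expect_lt(abs(peak_t - 2), 0.1)
  }
})

test_that("dropout counts follow the configured rate", {
  cfg <- gait_sim_config(duration = 100, dropout_rate = 0.01, rng_seed = 8)
  rec <- simulate_sensors(simulate_phase_timeline(cfg), cfg)
  n <- nrow(rec)
  expect_equal(n, 10000)
  expected <- n * 0.01
  band <- 3 * sqrt(n * 0.01 * 0.99)
  expect_lt(abs(sum(!rec$valid) - expected), band)
  expect_equal(sum(!rec$valid), attr(rec, "n_dropouts"))
})

test_that("the acceleration magnitude peaks at a jump", {
  cfg <- gait_sim_config(duration = 8, jump_times = 2, walk_onset = 6,
                         noise_sd = 0.05, dropout_rate = 0, rng_seed = 4)
  rec <- simulate_sensors(simulate_phase_timeline(cfg), cfg)
  mag <- sqrt(rec$acc_x^2 + rec$acc_y^2 + rec$acc_z^2)
  expect_lt(abs(rec$time[which.max(mag)] - 2), 0.2)
})

test_that("per-channel gains are reproducible and spread multiplicatively", {
  cfg <- quick_config(duration = 10, gain_spread = 0, noise_sd = 0,
                      dropout_rate = 0, outlier_rate = 0, drift_rate = 0)
  tl <- simulate_phase_timeline(cfg)
  a <- simulate_sensors(tl, cfg)
  b <- simulate_sensors(tl, cfg)
  expect_identical(a, b)
})
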