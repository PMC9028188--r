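test_that("NC removal keeps exactly the non-NC samples in order", {
  phases <- c(rep("NC", 40), rep("RSWLST", 30), rep("RSTLST", 30))
  rec <- make_recording(seq_len(100), phases)
  out <- drop_nc(rec)
  expect_equal(nrow(out), 60)
  expect_false(any(out$phase == "NC"))
  expect_equal(out$textile_01, 41:100) # order preserved
  expect_equal(stage_log(out)$n_out, 60L)

  clean <- make_recording(1:10, rep("RSTLST", 10))
  expect_equal(nrow(drop_nc(clean)), 10)

  all_nc <- make_recording(1:10, rep("NC", 10))
  expect_warning(empty <- drop_nc(all_nc), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("invalid and incomplete samples are removed", {
  rec <- make_recording(c(1, 2, NA, 4, 5), rep("RSTLST", 5),
                        valid = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  out <- drop_invalid(rec)
  expect_equal(out$textile_01, c(1, 4, 5))

  clean <- make_recording(1:5, rep("RSTLST", 5))
  expect_equal(nrow(drop_invalid(clean)), 5)
})

test_that("dropout bookkeeping matches the removed count", {
  cfg <- gait_sim_config(duration = 60, dropout_rate = 0.01, rng_seed = 3)
  rec <- simulate_sensors(simulate_phase_timeline(cfg), cfg)
  rec$phase <- factor("RSTLST", levels = gait_phases())
  out <- drop_invalid(rec)
  expect_equal(nrow(rec) - nrow(out), attr(rec, "n_dropouts"))
})

test_that("outlier replacement reproduces the documented rule", {
  x <- c(1, 2, 3, 2, 1, 100)
  y <- replace_outliers(x)
  expect_equal(y[1:5], x[1:5])
  expect_equal(y[6], mean(x[1:5]) + sd(x[1:5]))
  expect_equal(y[6], 2.6367, tolerance = 1e-3)

  no_out <- c(1, 2, 3, 4, 5)
  expect_identical(replace_outliers(no_out), no_out)

  # degenerate scaled MAD falls back to interquartile bounds
  const_spike <- c(5, 5, 5, 5, 5, 9)
  expect_warning(z <- replace_outliers(const_spike), "interquartile")
  expect_equal(z, c(5, 5, 5, 5, 5, 5))

  expect_error(replace_outliers(c(1, 2, 3)), "at least 4")
})

test_that("the low-pass filter matches its design response", {
  rate <- 100
  expect_lt(max(abs(lowpass(rep(7, 300), rate) - 7)), 1e-9)

  t <- seq(0, 3, by = 1 / rate)
  bf <- signal::butter(5, 20 / (rate / 2), type = "low")
  gain_at <- function(f) {
    h <- signal::freqz(bf, n = 512, Fs = rate)
    abs(h$h[which.min(abs(h$f - f))])
  }
  for (f in c(1, 40)) {
    x <- sin(2 * pi * f * t)
    ratio <- sqrt(mean(lowpass(x, rate)^2)) / sqrt(mean(x^2))
    expect_equal(ratio, gain_at(f), tolerance = 0.02)
  }
  # stated bounds: stopband < 5% of input RMS, passband within 2%
  x40 <- sin(2 * pi * 40 * t)
  expect_lt(sqrt(mean(lowpass(x40, rate)^2)) / sqrt(mean(x40^2)), 0.05)
  x1 <- sin(2 * pi * 1 * t)
  expect_equal(sqrt(mean(lowpass(x1, rate)^2)) / sqrt(mean(x1^2)), 1,
               tolerance = 0.02)

  expect_error(lowpass(rnorm(100), 30), "Nyquist")
})

test_that("causal filtering delays the signal, zero-phase does not", {
  rate <- 100
  t <- seq(0, 3, by = 1 / rate)
  x <- sin(2 * pi * 2 * t)
  lag_of <- function(y) {
    cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expect_equal(lag_of(lowpass(x, rate)), 0)
  causal <- lowpass(x, rate, preprocess_config(causal = TRUE))
  expect_gt(lag_of(causal), 0)
})

test_that("normalization centers and scales exactly", {
  expect_equal(normalize_channel(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(500, mean = 13, sd = 7)
  z <- normalize_channel(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_warning(z0 <- normalize_channel(rep(3, 10)), "constant")
  expect_equal(z0, rep(0, 10))
  expect_error(normalize_channel(1), "at least 2")
})

test_that("the full chain normalizes every channel and logs stage counts", {
  cfg <- gait_sim_config(duration = 30, rng_seed = 6)
  sim <- simulate_participant(cfg)
  labs <- generate_labels(sim$track)
  lr <- attach_labels(sim$recording, labs, sync_streams(sim$recording,
                                                        sim$track))
  out <- preprocess_recording(lr)
  for (ch in recording_channels(out)) {
    expect_lt(abs(mean(out[[ch]])), 1e-9)
    expect_lt(abs(sd(out[[ch]]) - 1), 1e-9)
  }
  lg <- stage_log(out)
  expect_equal(lg$stage, c("drop_nc", "drop_invalid", "condition"))
  expect_true(all(diff(c(lg$n_in[1], lg$n_out)) <= 0)) # monotone counts
})

test_that("ARFF export splits channels and round-trips", {
  phases <- rep(c("RSWLST", "RSTLSW", "RSTLST"), length.out = 30)
  rec <- make_recording(rnorm(30), phases,
                        more_channels = list(acc_z = rnorm(30)))
  dir <- withr::local_tempdir()
  paths <- split_and_export(rec, dir, "unit")
  tex <- read_gait_arff(paths[["textile"]])
  imu <- read_gait_arff(paths[["imu"]])
  expect_equal(nrow(tex), 30)
  expect_equal(nrow(imu), 30)
  expect_identical(tex$class, imu$class)
  expect_identical(as.character(tex$class), phases)
  expect_equal(tex$textile_01, rec$textile_01, tolerance = 1e-6)
  expect_equal(imu$acc_z, rec$acc_z, tolerance = 1e-6)

  expect_error(split_and_export(rec[0, ], dir), "empty")
})

test_that("an ARFF file without a class declaration is rejected", {
  f <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation x", "@attribute v numeric", "@data", "1.0", "2.0"),
             f)
  expect_error(read_gait_arff(f), "class")
  expect_silent(read_gait_arff(f, require_class = FALSE))
})
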