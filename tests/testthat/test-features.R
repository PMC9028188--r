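test_that("segmentation counts and labels follow the window rules", {
  rec <- make_recording(rnorm(1000), rep("RSWLST", 1000))
  inst <- segment_windows(rec, window_length = 50, stride = 25)
  expect_equal(nrow(inst), 39) # (1000 - 50) / 25 + 1
  expect_true(all(inst$label == "RSWLST"))

  # 70/30 boundary window takes the majority side
  rec2 <- make_recording(rnorm(50), c(rep("RSWLST", 35), rep("RSTLST", 15)))
  inst2 <- segment_windows(rec2, window_length = 50, stride = 50)
  expect_equal(as.character(inst2$label), "RSWLST")

  # a 50/50 tie is discarded
  rec3 <- make_recording(rnorm(50), c(rep("RSWLST", 25), rep("RSTLST", 25)))
  expect_equal(nrow(segment_windows(rec3, 50, 50)), 0)

  # NC-majority windows are discarded
  rec4 <- make_recording(rnorm(50), c(rep("NC", 40), rep("RSWLST", 10)))
  expect_equal(nrow(segment_windows(rec4, 50, 50)), 0)

  expect_error(segment_windows(rec2, window_length = 100), "exceeds")
})

test_that("windows never span removed-sample gaps", {
  rec <- make_recording(rnorm(100), rep("RSWLST", 100))
  rec <- rec[-(48:53), ] # cut a hole
  inst <- segment_windows(rec, window_length = 20, stride = 5)
  for (w in seq_len(nrow(inst))) {
    i0 <- which(abs(rec$time - inst$start_time[w]) < 1e-9)
    span <- rec$time[i0:(i0 + 19)]
    expect_lt(max(diff(span)), 1.5 / 100)
  }
})

test_that("the catalog has 22 statistics with documented exact values", {
  expect_length(feature_catalog(), 22)

  inst <- make_toy_instances(n_per_class = 2, w = 4, noise = 0)
  inst$window[[1]] <- matrix(c(1, 2, 3, 4), 4, 1,
                             dimnames = list(NULL, "textile_01"))
  ft <- suppressWarnings(extract_features(inst))
  expect_equal(ft$textile_01_mean[1], 2.5)
  expect_equal(ft$textile_01_slope[1], 1)
  expect_equal(ft$textile_01_sd[1], sd(1:4))

  # constant window: degenerate statistics are zeroed with a warning
  expect_warning(ftc <- extract_features(inst), "undefined")
  const_row <- 2 # untouched constant window
  expect_equal(ftc$textile_01_variance[const_row], 0)
  expect_equal(ftc$textile_01_zero_crossings[const_row], 0)
  expect_equal(ftc$textile_01_slope[const_row], 0)
  expect_false(any(!is.finite(as.matrix(ftc[, -1]))))
})

test_that("spectral features locate a pure tone", {
  w <- 20
  rate <- 100
  t <- (0:(w - 1)) / rate
  win <- matrix(sin(2 * pi * 10 * t), w, 1,
                dimnames = list(NULL, "textile_01"))
  inst <- make_toy_instances(n_per_class = 1, w = w, noise = 1)
  inst$window[[1]] <- win
  ft <- suppressWarnings(extract_features(inst, sensor_rate = rate))
  expect_equal(ft$textile_01_dominant_freq[1], 10)
  band_energy <- ft$textile_01_band_5_10[1] + ft$textile_01_band_10_20[1]
  total <- band_energy + ft$textile_01_band_0_5[1]
  expect_gt(band_energy / total, 0.95)
})

test_that("extraction is a pure function of the window, in row order", {
  inst <- make_toy_instances(n_per_class = 10, w = 10, noise = 1, seed = 3)
  ft <- extract_features(inst)
  perm <- rev(seq_len(nrow(inst)))
  inst_rev <- inst[perm, ]
  attr(inst_rev, "window_length") <- attr(inst, "window_length")
  attr(inst_rev, "channels") <- attr(inst, "channels")
  attr(inst_rev, "sensor_rate") <- attr(inst, "sensor_rate")
  ft_rev <- extract_features(inst_rev)
  expect_equal(as.data.frame(ft_rev), as.data.frame(ft[perm, ]),
               ignore_attr = TRUE)
})

test_that("relevance selection keeps separating features, drops pure noise", {
  set.seed(7)
  n <- 90
  label <- factor(rep(c("RSWLST", "RSTLSW", "RSTLST"), each = n / 3))
  tab <- tibble::tibble(
    label = label,
    separating = as.integer(label) * 5 + rnorm(n, sd = 0.1),
    duplicate = as.integer(label) * 5 + rnorm(n, sd = 0.1),
    noise = rnorm(n)
  )
  class(tab) <- c("gait_features", class(tab))
  sel <- select_relevant(tab, fdr_level = 0.05)
  rep <- selection_report(sel)
  expect_true(rep$kept[rep$feature == "separating"])
  expect_true(rep$kept[rep$feature == "duplicate"])
  expect_gt(rep$p_value[rep$feature == "noise"],
            rep$p_value[rep$feature == "separating"])
  expect_true(all(c("label", "separating", "duplicate") %in% names(sel)))

  single <- tab[tab$label == "RSWLST", ]
  expect_error(select_relevant(single), "2 classes")
})
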