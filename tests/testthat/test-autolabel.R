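test_that("landmark speed is zero for a stationary landmark", {
  trk <- make_track(50)
  sp <- estimate_landmark_speed(trk, "right_heel", labeler_config())
  expect_true(all(sp == 0))
})

test_that("landmark speed reproduces a known displacement rate", {
  # 0.7/60 normalized units per frame at 60 fps and 1 m per unit = 0.7 m/s
  trk <- make_track(50, right_step = 0.7 / 60 / 50) # keep x inside [0,1]
  cfg <- labeler_config(pixel_to_meter = 50, smoothing_window = 1)
  sp <- estimate_landmark_speed(trk, "right_heel", cfg)
  expect_equal(unique(round(sp, 10)), 0.7)
})

test_that("degenerate tracks are rejected", {
  trk <- make_track(1)
  expect_error(estimate_landmark_speed(trk, "right_heel"), "fewer than 2")
  expect_error(estimate_landmark_speed(make_track(10), "no_such"),
               "not present")
  bad <- make_track(10)
  bad$time <- rep(0, nrow(bad))
  expect_error(estimate_landmark_speed(bad, "right_heel"),
               "strictly increasing")
})

test_that("the frame rule maps speed patterns to classes", {
  cfg <- labeler_config(swing_speed_threshold = 0.35)
  expect_equal(classify_frame(0, 0, 0, 0, 0.5, cfg), "RSTLST")
  expect_equal(classify_frame(0.9, 0.8, 0.05, 0.05, 0.5, cfg), "RSWLST")
  expect_equal(classify_frame(0.05, 0.05, 0.9, 0.8, 0.5, cfg), "RSTLSW")
  # NC regardless of speeds outside the 15% margins
  expect_equal(classify_frame(0.9, 0.8, 0.05, 0.05, 0.10, cfg), "NC")
  expect_equal(classify_frame(0, 0, 0, 0, 0.90, cfg), "NC")
  # both feet apparently swinging: carry the previous label forward
  expect_equal(classify_frame(1, 1, 1, 1, 0.5, cfg, previous = "RSTLSW"),
               "RSTLSW")
  expect_error(classify_frame(NA, 0, 0, 0, 0.5, cfg), "finite")
})

test_that("a 10 s track yields one label event per 0.1 s", {
  cfg <- gait_sim_config(duration = 10, rng_seed = 1)
  trk <- simulate_keypoints(simulate_phase_timeline(cfg), cfg)
  labs <- generate_labels(trk, labeler_config())
  expect_equal(nrow(labs), 100)
  expect_equal(unique(round(diff(labs$time), 9)), 0.1)
  expect_error(generate_labels(trk[0, ]), "empty")
})

test_that("a track confined to the margin labels everything NC", {
  trk <- make_track(100, body_x = 0.05)
  labs <- generate_labels(trk, labeler_config())
  expect_true(all(labs$phase == "NC"))
})

test_that("noiseless labels agree with ground truth away from transitions", {
  cfg <- gait_sim_config(duration = 40, noise_sd = 0, keypoint_noise_sd = 0,
                         dropout_rate = 0, outlier_rate = 0, rng_seed = 5)
  tl <- simulate_phase_timeline(cfg)
  labs <- generate_labels(simulate_keypoints(tl, cfg), labeler_config())
  truth <- as.character(tl$phase)[findInterval(labs$time, tl$time)]
  transitions <- tl$time[which(diff(as.integer(tl$phase)) != 0) + 1]
  near <- vapply(labs$time, function(tt) {
    any(abs(tt - transitions) <= 2 / cfg$camera_rate)
  }, logical(1))
  agreement <- mean((as.character(labs$phase) == truth)[!near])
  expect_gte(agreement, 0.99)
})

test_that("labeler agreement does not improve as keypoint noise grows", {
  agree_at <- function(noise) {
    vals <- vapply(1:3, function(seed) {
      cfg <- gait_sim_config(duration = 30, keypoint_noise_sd = noise,
                             dropout_rate = 0, outlier_rate = 0,
                             rng_seed = seed)
      tl <- simulate_phase_timeline(cfg)
      labs <- generate_labels(simulate_keypoints(tl, cfg), labeler_config())
      truth <- as.character(tl$phase)[findInterval(labs$time, tl$time)]
      mean(as.character(labs$phase) == truth)
    }, numeric(1))
    mean(vals)
  }
  a0 <- agree_at(0)
  a1 <- agree_at(0.002)
  a2 <- agree_at(0.006)
  expect_gte(a0 + 0.01, a1)
  expect_gte(a1 + 0.01, a2)
})

test_that("double support is labeled with higher precision than swing", {
  per_class <- lapply(1:3, function(seed) {
    cfg <- gait_sim_config(duration = 60, keypoint_noise_sd = 5e-4,
                           dropout_rate = 0, outlier_rate = 0,
                           rng_seed = seed)
    tl <- simulate_phase_timeline(cfg)
    labs <- generate_labels(simulate_keypoints(tl, cfg), labeler_config())
    truth <- as.character(tl$phase)[findInterval(labs$time, tl$time)]
    score_precision(as.character(labs$phase), truth)$per_class
  })
  pc <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(per_class), class),
    precision = sum(tp) / sum(tp + fp))
  p <- setNames(pc$precision, pc$class)
  expect_gt(p[["RSTLST"]], p[["RSWLST"]])
  expect_gt(p[["RSTLST"]], p[["RSTLSW"]])
})

test_that("precision scoring matches hand counts and flags undefined", {
  # class A: 8 correct predictions, 2 false positives
  pred <- c(rep("RSWLST", 10), rep("RSTLST", 5))
  ref <- c(rep("RSWLST", 8), rep("RSTLST", 7))
  sc <- score_precision(pred, ref)
  expect_equal(sc$per_class$precision[sc$per_class$class == "RSWLST"], 0.8)
  expect_equal(sc$overall, 13 / 15)
  expect_equal(sc$overall, sum(diag(sc$confusion)) / sum(sc$confusion))

  perfect <- score_precision(ref, ref)
  expect_true(all(perfect$per_class$precision == 1))
  expect_equal(perfect$overall, 1)

  # RSTLSW occurs in the reference but is never predicted
  sc2 <- score_precision(rep("RSWLST", 4),
                         c("RSWLST", "RSWLST", "RSTLSW", "RSTLSW"))
  row <- sc2$per_class[sc2$per_class$class == "RSTLSW", ]
  expect_true(is.na(row$precision))
  expect_false(row$defined)

  expect_error(score_precision(pred, ref[-1]), "length mismatch")
})
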