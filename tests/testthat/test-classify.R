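test_that("the default split assigns one fifth of instances to test", {
  inst <- make_toy_instances(n_per_class = 50, w = 10)
  parts <- split_instances(inst, 0.2, mode = "block")
  expect_equal(parts$test_fraction_achieved, 0.2, tolerance = 0.02 / 0.2)
  expect_equal(nrow(parts$test) + nrow(parts$train), 100)

  r1 <- split_instances(inst, 0.2, mode = "random", seed = 9)
  r2 <- split_instances(inst, 0.2, mode = "random", seed = 9)
  expect_identical(r1$test$start_time, r2$test$start_time)

  single <- inst[inst$label == "a", ]
  expect_error(split_instances(single), "2 classes")
})

test_that("block splits keep overlapping windows on one side", {
  # windows with 50% overlap: stride = w/2; a window straddles the boundary
  # iff train and test contain start times closer than one window
  inst <- make_toy_instances(n_per_class = 40, w = 10)
  inst$start_time <- seq_len(nrow(inst)) * 0.05 # overlapping starts
  inst <- inst[order(inst$start_time), ]
  parts <- split_instances(inst, 0.2, mode = "block")
  expect_gt(min(parts$test$start_time), max(parts$train$start_time))
})

test_that("interval transform matches hand-computed mean, sd and slope", {
  X <- matrix(c(1, 2, 3, 4), 1, 4) # one instance, one channel, w = 4
  f <- gaitwear:::.tsf_transform(X, 4L, 1L, 1L, 4L)
  expect_equal(as.numeric(f), c(2.5, sd(1:4), 1))
  expect_equal(f[2], 1.2909944, tolerance = 1e-6)
  # sub-interval [2, 4]
  f2 <- gaitwear:::.tsf_transform(X, 4L, 1L, 2L, 4L)
  expect_equal(as.numeric(f2), c(3, 1, 1))
})

test_that("a single-tree full-window TSF equals a plain decision tree", {
  w <- 10
  inst <- make_toy_instances(n_per_class = 10,
                             levels_ = c(RSWLST = 0, RSTLSW = 5), w = w,
                             channels = c("textile_01", "textile_02"),
                             noise = 2, seed = 11)
  parts <- split_instances(inst, 0.25, mode = "random", seed = 2)

  tsf <- fit_tsf(parts$train,
                 tsf_config(n_trees = 1, n_intervals = 1,
                            min_interval_length = w, bootstrap = FALSE))
  got <- predict(tsf, parts$test)

  # independent route: hand-computed full-window (mean, sd, slope) features,
  # column order per channel (mean, sd, slope)
  hf <- function(set) {
    t(vapply(set$window, function(m) {
      unlist(lapply(seq_len(ncol(m)), function(ch) {
        col <- m[, ch]
        tt <- seq_along(col) - (length(col) + 1) / 2
        c(mean(col), sd(col), sum(tt * col) / sum(tt^2))
      }))
    }, numeric(3 * ncol(set$window[[1]]))))
  }
  cart <- fit_decision_tree(hf(parts$train), parts$train$label)
  want <- predict(cart, hf(parts$test))
  expect_identical(as.character(got), as.character(want))
})

test_that("constant-level classes are perfectly separable by TSF", {
  inst <- make_toy_instances(n_per_class = 20,
                             levels_ = c(RSWLST = 0, RSTLSW = 10),
                             w = 10, noise = 0.5)
  parts <- split_instances(inst, 0.2, mode = "random", seed = 1)
  m <- fit_tsf(parts$train, tsf_config(n_trees = 10, rng_seed = 3))
  expect_equal(mean(predict(m, parts$test) == parts$test$label), 1)
})

test_that("TSF window shorter than the minimum interval errors", {
  inst <- make_toy_instances(n_per_class = 5, w = 2)
  expect_error(fit_tsf(inst, tsf_config(min_interval_length = 3)), "shorter")
})

test_that("TSF is deterministic given its seed", {
  inst <- make_toy_instances(n_per_class = 15, w = 8, noise = 3, seed = 5)
  m1 <- fit_tsf(inst, tsf_config(n_trees = 5, rng_seed = 7))
  m2 <- fit_tsf(inst, tsf_config(n_trees = 5, rng_seed = 7))
  expect_identical(predict(m1, inst), predict(m2, inst))
})

test_that("the random forest separates a linear toy problem", {
  set.seed(2)
  tab <- tibble::tibble(
    label = factor(rep(c("RSWLST", "RSTLSW"), each = 30)),
    f1 = c(rnorm(30, 0), rnorm(30, 6)),
    f2 = rnorm(60)
  )
  rf <- fit_random_forest(tab, seed = 1)
  expect_equal(mean(predict(rf, tab) == tab$label), 1)

  rf2 <- fit_random_forest(tab, seed = 1)
  expect_identical(predict(rf2, tab), predict(rf, tab))

  bad <- tab
  bad$f1[1] <- NA
  expect_error(fit_random_forest(bad), "non-finite")
})

test_that("evaluation reports conserve counts and match hand arithmetic", {
  inst <- make_toy_instances(n_per_class = 20,
                             levels_ = c(RSWLST = 0, RSTLSW = 10),
                             w = 10, noise = 0.5)
  parts <- split_instances(inst, 0.2, mode = "random", seed = 1)
  m <- fit_tsf(parts$train, tsf_config(n_trees = 5))
  ev <- evaluate_model(m, parts$test)
  expect_equal(as.integer(rowSums(ev$confusion)),
               ev$per_class$support)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_true(all(ev$per_class$precision == 1))

  # hand-checked 2x2 confusion: [[8,2],[1,9]]
  pred <- c(rep("A", 8), rep("B", 2), "A", rep("B", 9))
  truth <- c(rep("A", 10), rep("B", 10))
  sc <- score_precision(pred, truth)
  pa <- sc$per_class$precision[sc$per_class$class == "A"]
  pb <- sc$per_class$precision[sc$per_class$class == "B"]
  expect_equal(pa, 8 / 9)
  expect_equal(pb, 9 / 11)
})

test_that("classifier precision improves as simulation noise vanishes", {
  run_at <- function(noise) {
    cfg <- gait_sim_config(duration = 60, noise_sd = noise,
                           gain_spread = noise, rng_seed = 31)
    pp <- gaitwear:::prepare_participant(cfg, labeler_config(),
                                         preprocess_config(), 20, 10, "p")
    tex <- gaitwear:::instances_channels(
      pp$instances,
      grep("^textile", attr(pp$instances, "channels"), value = TRUE))
    parts <- split_instances(tex, 0.2, mode = "block")
    feats_train <- suppressWarnings(extract_features(parts$train))
    feats_test <- suppressWarnings(extract_features(parts$test))
    rf <- fit_random_forest(feats_train, seed = 5)
    evaluate_model(rf, feats_test)$macro_precision
  }
  lo <- run_at(0.02)
  hi <- run_at(1.0)
  expect_gte(lo + 0.02, hi)
  expect_gt(lo, 0.85)
})
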