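#' Simulate one participant's complete trial
#'
#' Convenience wrapper producing the ground-truth timeline, the keypoint
#' track and the sensor recording for one configuration.
#'
#' @param config A [gait_sim_config()].
#' @return List with elements `timeline`, `track`, `recording`.
#' @export
simulate_participant <- function(config) {
  timeline <- simulate_phase_timeline(config)
  list(
    timeline = timeline,
    track = simulate_keypoints(timeline, config),
    recording = simulate_sensors(timeline, config)
  )
}

# full per-participant chain: simulate -> label -> sync -> attach ->
# preprocess -> segment
prepare_participant <- function(cfg, labeler, prep, window_length, stride,
                                id = "participant_1") {
  sim <- simulate_participant(cfg)
  labels <- generate_labels(sim$track, labeler)
  sync <- sync_streams(sim$recording, sim$track)
  labeled <- attach_labels(sim$recording, labels, sync)
  conditioned <- suppressWarnings(preprocess_recording(labeled, prep))
  instances <- segment_windows(conditioned, window_length, stride,
                               recording_id = id)
  list(sim = sim, labels = labels, sync = sync, labeled = labeled,
       conditioned = conditioned, instances = instances, id = id)
}

# concatenate instance sets, preserving segmentation attributes
bind_instances <- function(sets) {
  out <- dplyr::bind_rows(lapply(sets, as.data.frame))
  out <- tibble::as_tibble(out)
  for (a in c("window_length", "stride", "channels", "sensor_rate")) {
    attr(out, a) <- attr(sets[[1]], a)
  }
  class(out) <- unique(c("gait_instances", class(out)))
  out
}

# per-participant + pooled datasets for both channel subsets
benchmark_datasets <- function(instance_sets) {
  n <- length(instance_sets)
  all_chans <- attr(instance_sets[[1]], "channels")
  tex_chans <- grep("^textile", all_chans, value = TRUE)
  datasets <- list()
  for (set in c("textile", "imu")) {
    chans <- if (set == "textile") tex_chans else setdiff(all_chans, tex_chans)
    subs <- lapply(instance_sets, instances_channels, channels = chans)
    for (p in seq_len(n)) {
      datasets[[sprintf("participant_%d_%s", p, set)]] <- subs[[p]]
    }
    datasets[[sprintf("pooled_%s", set)]] <- bind_instances(subs)
  }
  datasets
}

# train and evaluate both classifiers on each dataset
benchmark_core <- function(datasets, seed, fdr_level, test_fraction, tsf,
                           rf_trees) {
  rows <- list()
  evaluations <- list()
  selected_features <- integer(0)
  selection_reports <- list()
  for (ds in names(datasets)) {
    parts <- split_instances(datasets[[ds]], test_fraction, mode = "block")

    feats_train <- suppressWarnings(extract_features(parts$train))
    feats_sel <- select_relevant(feats_train, fdr_level)
    kept <- attr(feats_sel, "feature_names")
    selected_features[ds] <- length(kept)
    selection_reports[[ds]] <- selection_report(feats_sel)
    feats_test <- suppressWarnings(extract_features(parts$test))
    feats_test <- feats_test[, c("label", kept), drop = FALSE]

    rf <- fit_random_forest(feats_sel, seed = child_seed(seed, "rf", ds),
                            num_trees = rf_trees)
    ev_rf <- evaluate_model(rf, feats_test)

    tsf_cfg <- tsf
    tsf_cfg$rng_seed <- child_seed(seed, "tsf", ds)
    tsf_model <- fit_tsf(parts$train, tsf_cfg)
    ev_tsf <- evaluate_model(tsf_model, parts$test)

    for (alg in c("random_forest", "time_series_forest")) {
      ev <- if (alg == "random_forest") ev_rf else ev_tsf
      evaluations[[paste(ds, alg, sep = ".")]] <- ev
      rows[[length(rows) + 1]] <- tibble::tibble(
        dataset = ds,
        sensor_set = if (grepl("textile$", ds)) "textile" else "imu",
        algorithm = alg,
        accuracy = ev$accuracy,
        macro_precision = ev$macro_precision,
        n_train = nrow(parts$train),
        n_test = nrow(parts$test),
        n_features = length(kept)
      )
    }
  }
  list(precision = dplyr::bind_rows(rows), evaluations = evaluations,
       selected_features = selected_features,
       selection_reports = selection_reports)
}

#' Run the full simulated classification benchmark
#'
#' Simulates `n_participants` walking trials, labels each with the rule-based
#' labeler, synchronizes and attaches the labels to the sensor stream,
#' preprocesses, segments into windows, and then builds
#' `2 * (n_participants + 1)` datasets: per-participant and pooled, for the
#' textile-only and IMU-only channel subsets. On every dataset both
#' classifiers are trained on a block-wise 80/20 split: a random forest on
#' the extracted-and-selected feature table, and a time series forest on the
#' raw windows. Feature relevance selection is computed on the training
#' partition only.
#'
#' @param n_participants Number of simulated participants.
#' @param duration Trial length per participant, seconds.
#' @param seed Root seed; all stage seeds derive from it.
#' @param sim_args Named list of overrides passed to [gait_sim_config()].
#' @param labeler A [labeler_config()].
#' @param prep A [preprocess_config()].
#' @param window_length,stride Segmentation parameters (samples).
#' @param fdr_level Feature-selection false-discovery level.
#' @param test_fraction Test share of the train/test split.
#' @param tsf A [tsf_config()]; its seed is re-derived per dataset.
#' @param rf_trees Random-forest size.
#' @return A `gait_benchmark` object: `precision` table (one row per dataset
#'   x algorithm), named `evaluations` list of [evaluate_model()] reports,
#'   `stage_logs`, and `selected_features` counts.
#' @export
run_experiment <- function(n_participants = 3, duration = 180, seed = 1L,
                           sim_args = list(), labeler = labeler_config(),
                           prep = preprocess_config(),
                           window_length = 20, stride = 10,
                           fdr_level = 0.05, test_fraction = 0.2,
                           tsf = tsf_config(), rf_trees = 500) {
  preps <- lapply(seq_len(n_participants), function(p) {
    args <- utils::modifyList(list(
      duration = duration,
      rng_seed = child_seed(seed, "participant", p),
      camera_clock_offset = 1.5 * p
    ), sim_args)
    cfg <- do.call(gait_sim_config, args)
    prepare_participant(cfg, labeler, prep, window_length, stride,
                        id = sprintf("participant_%d", p))
  })

  datasets <- benchmark_datasets(lapply(preps, `[[`, "instances"))
  core <- benchmark_core(datasets, seed, fdr_level, test_fraction, tsf,
                         rf_trees)

  stage_logs <- lapply(preps, function(pp) stage_log(pp$conditioned))
  names(stage_logs) <- vapply(preps, `[[`, "", "id")

  out <- c(core, list(stage_logs = stage_logs,
                      n_participants = n_participants, seed = seed))
  class(out) <- "gait_benchmark"
  out
}

#' @export
print.gait_benchmark <- function(x, ...) {
  cat(sprintf("<gait_benchmark> %d participants, %d datasets, %d evaluations\n",
              x$n_participants, length(x$selected_features),
              length(x$evaluations)))
  print(as.data.frame(x$precision))
  invisible(x)
}

#' @export
tidy.gait_benchmark <- function(x, ...) x$precision

#' @export
glance.gait_benchmark <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$precision, .data$algorithm, .data$sensor_set),
    macro_precision = mean(.data$macro_precision),
    accuracy = mean(.data$accuracy), .groups = "drop")
}

#' Off-diagonal confusion summary of an evaluation
#'
#' Summarizes the two structurally different error types of the three-class
#' problem: confusion between the two single-support classes
#' (`swing_swing`), and confusion between either single-support class and
#' double support (`swing_double`), both as mean row-normalized rates.
#'
#' @param ev A `gait_eval` with all three walking classes.
#' @return Tibble with columns `swing_swing` and `swing_double`.
#' @export
swing_confusion <- function(ev) {
  cn <- ev$confusion_rownorm
  need <- c("RSWLST", "RSTLSW", "RSTLST")
  if (!all(need %in% rownames(cn))) {
    stopf("evaluation does not cover all three walking classes")
  }
  tibble::tibble(
    swing_swing = mean(c(cn["RSWLST", "RSTLSW"], cn["RSTLSW", "RSWLST"])),
    swing_double = mean(c(cn["RSWLST", "RSTLST"], cn["RSTLSW", "RSTLST"],
                          cn["RSTLST", "RSWLST"], cn["RSTLST", "RSTLSW"]))
  )
}
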