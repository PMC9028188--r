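# small, fast simulation configurations and hand-built fixtures

quick_config <- function(...) {
  args <- utils::modifyList(list(duration = 20, rng_seed = 1), list(...))
  do.call(gait_sim_config, args)
}

# a bare labeled recording built by hand (one textile channel), for
# segmentation and preprocessing tests that need full control over phases
make_recording <- function(values, phases, rate = 100, valid = NULL,
                           more_channels = NULL) {
  n <- length(values)
  df <- tibble::tibble(
    time = seq(0, by = 1 / rate, length.out = n),
    textile_01 = values
  )
  if (!is.null(more_channels)) {
    for (nm in names(more_channels)) df[[nm]] <- more_channels[[nm]]
  }
  df$valid <- valid %||% rep(TRUE, n)
  df$phase <- factor(phases, levels = gait_phases())
  chans <- setdiff(names(df), c("time", "valid", "phase"))
  structure(df,
            class = c("gait_labeled_recording", "gait_recording", class(df)),
            sensor_rate = rate,
            textile_channels = grep("^textile", chans, value = TRUE),
            imu_channels = grep("^textile", chans, value = TRUE,
                                invert = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal keypoint track with the landmarks the labeler needs, where both
# feet move with given per-frame displacements (normalized units)
make_track <- function(n_frames, rate = 60, right_step = 0, left_step = 0,
                       body_x = 0.5) {
  t <- seq(0, by = 1 / rate, length.out = n_frames)
  lm <- c("right_heel", "right_foot_index", "left_heel", "left_foot_index",
          "left_hip", "right_hip")
  rows <- lapply(lm, function(l) {
    step <- if (grepl("^right_(heel|foot)", l)) right_step
            else if (grepl("^left_(heel|foot)", l)) left_step else 0
    tibble::tibble(time = t, landmark = l,
                   x = if (grepl("hip", l)) rep(body_x, n_frames)
                       else 0.3 + step * (seq_len(n_frames) - 1),
                   y = 0.8, visibility = 1)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), time, landmark)
  structure(out, class = c("gait_track", class(out)), camera_rate = rate)
}

# toy instance set: constant windows at class-specific levels plus noise
make_toy_instances <- function(n_per_class = 20, levels_ = c(a = 0, b = 10),
                               w = 10, channels = c("textile_01"),
                               noise = 0.5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cl in names(levels_)) {
    for (i in seq_len(n_per_class)) {
      m <- matrix(levels_[[cl]] + rnorm(w * length(channels), sd = noise),
                  w, length(channels), dimnames = list(NULL, channels))
      rows[[length(rows) + 1]] <- list(window = m, label = cl)
    }
  }
  out <- tibble::tibble(
    window = lapply(rows, `[[`, "window"),
    label = factor(vapply(rows, `[[`, "", "label")),
    start_time = seq_along(rows) * 0.1,
    recording_id = "toy"
  )
  # interleave the classes in time so block splits see every class
  ord <- order(rep(seq_len(n_per_class), times = length(levels_)))
  out <- out[ord, ]
  out$start_time <- seq_len(nrow(out)) * 0.1
  structure(out, class = c("gait_instances", class(out)),
            window_length = as.integer(w), stride = as.integer(w),
            channels = channels, sensor_rate = 100)
}
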