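#' Configuration for the rule-based gait-phase labeler
#'
#' The labeler estimates heel and toe speeds from consecutive keypoint frames
#' and classifies each instant into one of the three walking classes, or `NC`
#' when the body center lies inside the horizontal image margins where the
#' participant turns around.
#'
#' The swing speed threshold defaults to 0.35 m/s, half the nominal 0.7 m/s
#' walking pace: a stance foot is essentially stationary while a swing foot
#' moves well above the body speed, so the midpoint of 0 and the pace
#' separates the two regimes. `pixel_to_meter` converts normalized image
#' units to meters and defaults to the value implied by a 3.5 m path spanning
#' the central 86% of the frame.
#'
#' @param pixel_to_meter Meters per normalized image unit.
#' @param swing_speed_threshold Speed (m/s) above which a foot counts as
#'   swinging.
#' @param nc_margin_fraction Horizontal margin (fraction of frame width) of
#'   the `NC` rule.
#' @param label_rate Label emission rate in Hz.
#' @param smoothing_window Moving-average window (frames) applied to the
#'   speed estimates; 1 disables smoothing.
#' @return A `labeler_config` list.
#' @export
#' @examples
#' labeler_config()$swing_speed_threshold
labeler_config <- function(pixel_to_meter = default_pixel_to_meter(),
                           swing_speed_threshold = 0.35,
                           nc_margin_fraction = 0.15,
                           label_rate = 10,
                           smoothing_window = 3) {
  if (pixel_to_meter <= 0) stopf("`pixel_to_meter` must be > 0")
  if (swing_speed_threshold <= 0) stopf("`swing_speed_threshold` must be > 0")
  if (nc_margin_fraction <= 0 || nc_margin_fraction >= 0.5) {
    stopf("`nc_margin_fraction` must lie in (0, 0.5)")
  }
  if (label_rate <= 0) stopf("`label_rate` must be > 0")
  if (smoothing_window < 1) stopf("`smoothing_window` must be >= 1")
  structure(list(
    pixel_to_meter = pixel_to_meter,
    swing_speed_threshold = swing_speed_threshold,
    nc_margin_fraction = nc_margin_fraction,
    label_rate = label_rate,
    smoothing_window = as.integer(smoothing_window)
  ), class = "labeler_config")
}

#' Estimate the speed of one landmark over a track
#'
#' The speed at frame i is the Euclidean displacement from frame i-1 divided
#' by the time step, converted to m/s with `pixel_to_meter`; the first frame
#' inherits the second frame's speed. An optional centered moving average
#' over `smoothing_window` frames damps frame-to-frame pose jitter.
#'
#' @param track A `gait_track` (long tibble `time`, `landmark`, `x`, `y`).
#' @param landmark Landmark name present in the track.
#' @param config A [labeler_config()].
#' @return Numeric vector of per-frame speeds (m/s), one per frame.
#' @export
#' @examples
#' cfg <- gait_sim_config(duration = 8)
#' trk <- simulate_keypoints(simulate_phase_timeline(cfg), cfg)
#' sp <- estimate_landmark_speed(trk, "right_heel", labeler_config())
estimate_landmark_speed <- function(track, landmark, config = labeler_config()) {
  sub <- track[track$landmark == landmark, , drop = FALSE]
  if (nrow(sub) == 0) stopf("landmark '%s' not present in track", landmark)
  if (nrow(sub) < 2) stopf("track has fewer than 2 frames for '%s'", landmark)
  ts <- sub$time
  if (any(diff(ts) <= 0)) stopf("track timestamps must be strictly increasing")
  disp <- sqrt(diff(sub$x)^2 + diff(sub$y)^2)
  speed <- config$pixel_to_meter * disp / diff(ts)
  speed <- c(speed[1], speed)
  moving_average(speed, config$smoothing_window)
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1) %/% 2
  pad <- c(rep(x[1], half), x, rep(x[n], w - 1 - half))
  as.numeric(stats::filter(pad, rep(1 / w, w), sides = 1))[w:(w + n - 1)]
}

#' Classify one instant from foot speeds and body position
#'
#' Applies the labeling rule: `NC` if the body center lies inside the
#' horizontal image margins; otherwise a foot is swinging iff the larger of
#' its heel and toe speeds exceeds the threshold, and the swing pattern maps
#' to the class. A frame where both feet appear to swing is physically
#' impossible in walking (there is no flight phase), so the previous label is
#' carried forward.
#'
#' @param right_heel,right_toe,left_heel,left_toe Speeds in m/s.
#' @param body_center_x Normalized image x of the body center.
#' @param config A [labeler_config()].
#' @param previous Label to fall back on when both feet appear to swing.
#' @return A single gait-phase label (character).
#' @export
#' @examples
#' classify_frame(0.9, 0.8, 0.05, 0.05, 0.5, labeler_config())
classify_frame <- function(right_heel, right_toe, left_heel, left_toe,
                           body_center_x, config = labeler_config(),
                           previous = "RSTLST") {
  speeds <- c(right_heel, right_toe, left_heel, left_toe)
  if (any(!is.finite(speeds))) stopf("all four speeds must be finite")
  classify_speeds(right_heel, right_toe, left_heel, left_toe, body_center_x,
                  config, previous)
}

# vectorized rule; `previous` resolves both-swing frames sequentially
classify_speeds <- function(rh, rt, lh, lt, body_x, config,
                            previous = "RSTLST") {
  right_swing <- pmax(rh, rt) > config$swing_speed_threshold
  left_swing <- pmax(lh, lt) > config$swing_speed_threshold
  nc <- body_x < config$nc_margin_fraction |
    body_x > 1 - config$nc_margin_fraction
  out <- character(length(rh))
  out[!right_swing & !left_swing] <- "RSTLST"
  out[right_swing & !left_swing] <- "RSWLST"
  out[!right_swing & left_swing] <- "RSTLSW"
  both <- right_swing & left_swing
  prev <- previous
  for (i in seq_along(out)) {
    if (both[i]) out[i] <- prev else prev <- out[i]
    if (nc[i]) out[i] <- "NC"
  }
  out
}

#' Generate a 10 Hz label stream from a keypoint track
#'
#' Emits one label event every `1/label_rate` seconds across the track span.
#' Each event is classified from the frame nearest in time, using the smoothed
#' heel/toe speeds of both feet and the mean hip x-coordinate as body center.
#'
#' @param track A non-empty `gait_track`.
#' @param config A [labeler_config()].
#' @return A `gait_labels` tibble with columns `time` (s, on the track's
#'   clock) and `phase`.
#' @export
#' @examples
#' cfg <- gait_sim_config(duration = 10)
#' trk <- simulate_keypoints(simulate_phase_timeline(cfg), cfg)
#' labs <- generate_labels(trk, labeler_config())
#' nrow(labs)
generate_labels <- function(track, config = labeler_config()) {
  if (is.null(track) || nrow(track) == 0) stopf("track is empty")
  frames <- sort(unique(track$time))
  if (length(frames) < 2) stopf("track has fewer than 2 frames")

  rh <- estimate_landmark_speed(track, "right_heel", config)
  rt <- estimate_landmark_speed(track, "right_foot_index", config)
  lh <- estimate_landmark_speed(track, "left_heel", config)
  lt <- estimate_landmark_speed(track, "left_foot_index", config)

  lh_x <- track[track$landmark == "left_hip", ]
  rh_x <- track[track$landmark == "right_hip", ]
  if (nrow(lh_x) == 0 || nrow(rh_x) == 0) {
    stopf("track must contain 'left_hip' and 'right_hip' landmarks")
  }
  body_x <- (lh_x$x[match(frames, lh_x$time)] +
               rh_x$x[match(frames, rh_x$time)]) / 2

  event_times <- seq(frames[1], frames[length(frames)],
                     by = 1 / config$label_rate)
  idx <- vapply(event_times, function(tt) which.min(abs(frames - tt)),
                integer(1))

  labels <- classify_speeds(rh[idx], rt[idx], lh[idx], lt[idx], body_x[idx],
                            config)
  out <- tibble::tibble(time = event_times, phase = phase_factor(labels))
  structure(out, class = c("gait_labels", class(out)),
            label_rate = config$label_rate)
}

#' Per-class and overall precision of a label sequence
#'
#' Compares aligned predicted and reference label sequences. Per class,
#' precision is the number of true positives divided by all positive
#' predictions for that class; a class that is never predicted has undefined
#' precision and is reported as `NA` with `defined = FALSE` rather than zero.
#' Overall precision is the fraction of events predicted correctly (the trace
#' of the count confusion matrix over its total).
#'
#' @param predicted,reference Equal-length label vectors (or `gait_labels`
#'   tibbles, from which the `phase` column is taken).
#' @return A `gait_precision` object: list with `per_class` (tibble),
#'   `overall`, and the count `confusion` matrix (rows = reference).
#' @export
#' @examples
#' score_precision(c("RSTLST", "RSWLST"), c("RSTLST", "RSWLST"))$overall
score_precision <- function(predicted, reference) {
  if (inherits(predicted, "data.frame")) predicted <- predicted$phase
  if (inherits(reference, "data.frame")) reference <- reference$phase
  if (length(predicted) != length(reference)) {
    stopf("length mismatch: %d predicted vs %d reference events",
          length(predicted), length(reference))
  }
  pred <- as.character(predicted)
  ref <- as.character(reference)
  lev <- if (all(c(pred, ref) %in% gait_phases())) {
    gait_phases()
  } else {
    sort(unique(c(pred, ref)))
  }
  present <- lev[lev %in% c(pred, ref)]
  confusion <- table(reference = factor(ref, present),
                     predicted = factor(pred, present))
  tp <- unname(diag(confusion))
  pred_n <- unname(colSums(confusion))
  per_class <- tibble::tibble(
    class = present,
    tp = as.integer(tp),
    fp = as.integer(pred_n - tp),
    support = as.integer(unname(rowSums(confusion))),
    precision = ifelse(pred_n > 0, tp / pred_n, NA_real_),
    defined = pred_n > 0
  )
  out <- list(per_class = per_class,
              overall = mean(pred == ref),
              confusion = confusion)
  class(out) <- "gait_precision"
  out
}

#' @export
print.gait_precision <- function(x, ...) {
  cat(sprintf("<gait_precision> overall %.3f\n", x$overall))
  print(as.data.frame(x$per_class))
  invisible(x)
}

#' @export
tidy.gait_precision <- function(x, ...) x$per_class

#' @export
glance.gait_precision <- function(x, ...) {
  tibble::tibble(
    overall_precision = x$overall,
    macro_precision = mean(x$per_class$precision, na.rm = TRUE),
    n_events = sum(x$per_class$support)
  )
}
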