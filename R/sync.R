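#' Detect synchronization jumps in a signal
#'
#' Finds the `expected_count` most prominent excursions of the detrended,
#' rectified signal, requiring each pair of detections to be at least
#' `min_separation` seconds apart. Used on the acceleration magnitude of a
#' sensor recording, the summed textile channels of a textile-only recording,
#' or the (inverted) mean heel height of a keypoint track, all of which spike
#' simultaneously at each pre-trial jump.
#'
#' @param x A `gait_recording`, `gait_track`, or numeric signal vector.
#' @param expected_count Number of jumps to find.
#' @param min_separation Minimum spacing between jumps, seconds.
#' @param time Timestamps (required for the numeric method).
#' @param ... Passed to methods.
#' @return Numeric vector of jump times (on the stream's own clock), in time
#'   order.
#' @export
detect_jumps <- function(x, expected_count = 3, min_separation = 0.5, ...) {
  UseMethod("detect_jumps")
}

#' @rdname detect_jumps
#' @export
detect_jumps.numeric <- function(x, expected_count = 3, min_separation = 0.5,
                                 time = NULL, ...) {
  if (length(x) == 0) stopf("signal is empty")
  if (expected_count < 1) stopf("`expected_count` must be >= 1")
  if (is.null(time)) stopf("`time` is required for a bare numeric signal")
  x[!is.finite(x)] <- NA
  med <- median(x, na.rm = TRUE)
  z <- abs(x - med)
  z[is.na(z)] <- 0
  thr <- median(z) + 5 * mad(z)
  dt <- median(diff(time))
  radius <- max(1L, as.integer(round(min_separation / dt)))

  found <- numeric(0)
  zz <- z
  for (k in seq_len(expected_count)) {
    i <- which.max(zz)
    if (zz[i] <= thr || zz[i] == 0) break
    found <- c(found, time[i])
    lo <- max(1L, i - radius)
    hi <- min(length(zz), i + radius)
    zz[lo:hi] <- 0
  }
  if (length(found) < expected_count) {
    stopf("expected %d synchronization peaks but found only %d",
          expected_count, length(found))
  }
  sort(found)
}

#' @rdname detect_jumps
#' @export
detect_jumps.gait_recording <- function(x, expected_count = 3,
                                        min_separation = 0.5, ...) {
  imu <- recording_channels(x, "imu")
  acc <- intersect(c("acc_x", "acc_y", "acc_z"), imu)
  sig <- if (length(acc) >= 1) {
    sqrt(rowSums(as.matrix(x[, acc, drop = FALSE])^2))
  } else {
    rowSums(as.matrix(x[, recording_channels(x, "textile"), drop = FALSE]))
  }
  detect_jumps(as.numeric(sig), expected_count, min_separation, time = x$time)
}

#' @rdname detect_jumps
#' @export
detect_jumps.gait_track <- function(x, expected_count = 3,
                                    min_separation = 0.5, ...) {
  heels <- x[x$landmark %in% c("left_heel", "right_heel"), ]
  frames <- sort(unique(heels$time))
  lh <- heels$y[heels$landmark == "left_heel"][match(frames,
    heels$time[heels$landmark == "left_heel"])]
  rh <- heels$y[heels$landmark == "right_heel"][match(frames,
    heels$time[heels$landmark == "right_heel"])]
  # jumps lift both heels: y decreases, so invert
  detect_jumps(-(lh + rh), expected_count, min_separation, time = frames)
}

#' Align the label clock to the acquisition clock
#'
#' Pairs the jump times detected in the label/track stream with those from
#' the sensor stream (both in time order) and estimates the clock offset as
#' the mean pairwise difference (label minus sensor). The residual is the
#' largest deviation of a pairwise difference from that mean, a diagnostic
#' for mismatched jump detections.
#'
#' @param label_jumps,sensor_jumps Equal-length vectors of jump times.
#' @return A `gait_sync` list: `clock_offset` (s), `residual` (s),
#'   `jump_times_track`, `jump_times_sensor`.
#' @export
#' @examples
#' align_jumps(c(3.4, 4.5, 5.6), c(1.0, 2.0, 3.0))$clock_offset
align_jumps <- function(label_jumps, sensor_jumps) {
  if (length(label_jumps) != length(sensor_jumps)) {
    stopf("jump count mismatch: %d vs %d", length(label_jumps),
          length(sensor_jumps))
  }
  if (length(label_jumps) < 1) stopf("need at least one jump in each stream")
  d <- sort(label_jumps) - sort(sensor_jumps)
  offset <- mean(d)
  structure(list(
    clock_offset = offset,
    residual = max(abs(d - offset)),
    jump_times_track = sort(label_jumps),
    jump_times_sensor = sort(sensor_jumps)
  ), class = "gait_sync")
}

#' Detect jumps in both streams and align their clocks
#'
#' @param recording A `gait_recording`.
#' @param track A `gait_track` (or a precomputed vector of jump times on the
#'   label clock).
#' @param expected_count Number of synchronization jumps.
#' @param min_separation Minimum spacing between jumps, seconds.
#' @return A `gait_sync` object (see [align_jumps()]).
#' @export
sync_streams <- function(recording, track, expected_count = 3,
                         min_separation = 0.5) {
  sensor_jumps <- detect_jumps(recording, expected_count, min_separation)
  track_jumps <- if (is.numeric(track)) track else {
    detect_jumps(track, expected_count, min_separation)
  }
  align_jumps(track_jumps, sensor_jumps)
}

#' @export
print.gait_sync <- function(x, ...) {
  cat(sprintf("<gait_sync> clock offset %.4f s (residual %.4f s) from %d jumps\n",
              x$clock_offset, x$residual, length(x$jump_times_sensor)))
  invisible(x)
}

#' Attach 10 Hz labels to 100 Hz sensor samples
#'
#' Maps each sensor sample to its offset-corrected time on the label clock
#' and assigns the phase of the most recent label event at or before that
#' time (previous-observation carried forward; labels are categorical, so no
#' value interpolation is meaningful). Samples falling before the first or
#' after the last label event are marked `NC`. Sensor values and timestamps
#' are never modified.
#'
#' @param recording A `gait_recording`.
#' @param labels A `gait_labels` stream.
#' @param sync A `gait_sync` from [sync_streams()]/[align_jumps()], or a
#'   bare numeric clock offset (label minus sensor, seconds).
#' @return A `gait_labeled_recording`: the recording plus a `phase` column.
#' @export
attach_labels <- function(recording, labels, sync) {
  if (is.null(labels) || nrow(labels) == 0) stopf("label stream is empty")
  offset <- if (is.numeric(sync)) sync else sync$clock_offset
  # nanosecond slack so exact label/sample coincidence is not lost to
  # floating-point representation of the time grids
  t_label <- recording$time + offset + 1e-9
  idx <- findInterval(t_label, labels$time)
  phase <- rep("NC", nrow(recording))
  inside <- idx >= 1 & t_label <= max(labels$time) + 2e-9
  phase[inside] <- as.character(labels$phase)[idx[inside]]
  out <- recording
  out$phase <- phase_factor(phase)
  class(out) <- unique(c("gait_labeled_recording", class(recording)))
  attr(out, "clock_offset") <- offset
  out
}
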