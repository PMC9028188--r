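#' Configuration for the signal-conditioning chain
#'
#' @param filter_order Butterworth filter order.
#' @param cutoff_hz Low-pass cutoff frequency in Hz (must be below Nyquist).
#' @param outlier_k Scaled-MAD multiplier of the robust outlier rule.
#' @param causal If `TRUE`, apply the filter in a single forward pass
#'   (introduces group delay); the default is zero-phase forward-backward
#'   filtering, which keeps the filtered signal time-aligned with the labels.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(filter_order = 5, cutoff_hz = 20,
                              outlier_k = 3, causal = FALSE) {
  if (filter_order < 1) stopf("`filter_order` must be >= 1")
  if (cutoff_hz <= 0) stopf("`cutoff_hz` must be > 0")
  if (outlier_k <= 0) stopf("`outlier_k` must be > 0")
  structure(list(filter_order = as.integer(filter_order),
                 cutoff_hz = cutoff_hz, outlier_k = outlier_k,
                 causal = isTRUE(causal)),
            class = "preprocess_config")
}

#' Remove turnaround (`NC`) samples
#'
#' Drops every sample labeled `NC`, preserving order. The removed count is
#' recorded in the `stage_log` attribute.
#'
#' @param rec A `gait_labeled_recording`.
#' @return The recording without `NC` samples.
#' @export
drop_nc <- function(rec) {
  if (!"phase" %in% names(rec)) stopf("recording has no `phase` column")
  keep <- as.character(rec$phase) != "NC"
  out <- rec[keep, , drop = FALSE]
  if (nrow(out) == 0) warnf("all samples were NC; recording is now empty")
  log_stage(out, "drop_nc", nrow(rec), nrow(out))
}

#' Remove invalid or incomplete samples
#'
#' Drops samples flagged invalid (transmission dropouts) and samples with any
#' non-finite channel value, preserving order.
#'
#' @param rec A labeled or unlabeled `gait_recording`.
#' @return The recording without invalid samples.
#' @export
drop_invalid <- function(rec) {
  chans <- recording_channels(rec)
  ok <- if ("valid" %in% names(rec)) rec$valid else rep(TRUE, nrow(rec))
  finite <- rowSums(!is.finite(as.matrix(rec[, chans, drop = FALSE]))) == 0
  out <- rec[ok & finite, , drop = FALSE]
  log_stage(out, "drop_invalid", nrow(rec), nrow(out))
}

#' Robust outlier replacement for one channel
#'
#' A point is an outlier iff it deviates from the series median by more than
#' `k` scaled median absolute deviations (scale factor 1.4826, the
#' conventional consistency constant for normal data). Every outlier is
#' replaced by the mean plus the sample standard deviation of the non-outlier
#' points; non-outliers are returned unchanged. When the scaled MAD is zero
#' (more than half the points identical), the rule degenerates, so the
#' detector falls back to interquartile bounds (with a warning): points
#' outside `[q1 - 1.5 IQR, q3 + 1.5 IQR]` are flagged.
#'
#' @param x Numeric series of length >= 4.
#' @param k Scaled-MAD multiplier (default 3).
#' @return The series with outliers replaced.
#' @export
#' @examples
#' replace_outliers(c(1, 2, 3, 2, 1, 100))
replace_outliers <- function(x, k = 3) {
  if (length(x) < 4) stopf("series must have at least 4 points")
  med <- median(x, na.rm = TRUE)
  smad <- mad(x, na.rm = TRUE) # 1.4826 * median(|x - med|)
  if (smad > 0) {
    out <- abs(x - med) > k * smad
  } else {
    warnf("scaled MAD is zero; falling back to interquartile bounds")
    q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    out <- x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
  }
  out[is.na(out)] <- FALSE
  if (any(out)) {
    good <- x[!out]
    x[out] <- mean(good, na.rm = TRUE) + sd(good, na.rm = TRUE)
  }
  x
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero phase), after extending the series by odd reflection at both ends so
#' the filter state settles before the retained samples (the bare
#' forward-backward pass has large edge transients). With `causal = TRUE` a
#' single forward pass is used instead. DC gain is one: a constant series is
#' preserved to numerical tolerance.
#'
#' @param x Numeric series.
#' @param sensor_rate Sampling rate in Hz.
#' @param config A [preprocess_config()].
#' @return The filtered series.
#' @export
#' @examples
#' lowpass(rep(7, 300), 100)[1:3]
lowpass <- function(x, sensor_rate, config = preprocess_config()) {
  nyq <- sensor_rate / 2
  if (config$cutoff_hz >= nyq) {
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          config$cutoff_hz, nyq)
  }
  n <- length(x)
  bf <- signal::butter(config$filter_order, config$cutoff_hz / nyq,
                       type = "low")
  if (config$causal) {
    return(as.numeric(signal::filter(bf, x)))
  }
  if (n < 4) return(x)
  pad <- min(n - 1, max(12L, 36L * config$filter_order))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1):(pad + n)]
}

#' Z-normalize one channel
#'
#' Centers the series at mean 0 and scales it to sample standard deviation 1.
#' A constant series has undefined scale and is returned as all zeros with a
#' warning.
#'
#' @param x Numeric series of length >= 2.
#' @return The normalized series.
#' @export
#' @examples
#' normalize_channel(c(1, 2, 3))
normalize_channel <- function(x) {
  if (length(x) < 2) stopf("series must have at least 2 points")
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warnf("constant series: standard deviation undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Run the full conditioning chain on a labeled recording
#'
#' Applies, in order: `NC` removal, invalid-sample removal, per-channel
#' outlier replacement, zero-phase low-pass filtering, and per-channel
#' z-normalization. Channels are always processed independently. Per-stage
#' sample counts are accumulated in the `stage_log` attribute (see
#' [stage_log()]).
#'
#' @param rec A `gait_labeled_recording`.
#' @param config A [preprocess_config()].
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  rate <- attr(rec, "sensor_rate")
  if (is.null(rate)) rate <- 1 / median(diff(rec$time))
  out <- drop_nc(rec)
  out <- drop_invalid(out)
  chans <- recording_channels(out)
  if (nrow(out) >= 4) {
    for (ch in chans) {
      x <- replace_outliers(out[[ch]], config$outlier_k)
      x <- lowpass(x, rate, config)
      out[[ch]] <- normalize_channel(x)
    }
  }
  log_stage(out, "condition", nrow(out), nrow(out))
}

log_stage <- function(rec, stage, n_in, n_out) {
  log <- attr(rec, "stage_log")
  if (is.null(log)) {
    log <- tibble::tibble(stage = character(0), n_in = integer(0),
                          n_out = integer(0))
  }
  attr(rec, "stage_log") <- dplyr::bind_rows(
    log, tibble::tibble(stage = stage, n_in = as.integer(n_in),
                        n_out = as.integer(n_out)))
  rec
}

#' Per-stage sample counts of a preprocessed recording
#'
#' @param rec A recording that has passed through preprocessing stages.
#' @return A tibble with columns `stage`, `n_in`, `n_out`.
#' @export
stage_log <- function(rec) {
  attr(rec, "stage_log") %||%
    tibble::tibble(stage = character(0), n_in = integer(0), n_out = integer(0))
}

#' Split a preprocessed recording into textile and IMU ARFF files
#'
#' Writes two ARFF files with identical timestamps and class labels: one with
#' the textile channels, one with the IMU channels. Both round-trip through
#' [read_gait_arff()].
#'
#' @param rec A preprocessed `gait_labeled_recording`.
#' @param out_dir Output directory (created if needed).
#' @param basename File name stem; files are `<basename>_textile.arff` and
#'   `<basename>_imu.arff`.
#' @return Invisibly, a named character vector of the two file paths.
#' @export
split_and_export <- function(rec, out_dir, basename = "dataset") {
  if (nrow(rec) == 0) stopf("recording is empty; nothing to export")
  if (!"phase" %in% names(rec)) stopf("recording has no `phase` column")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    textile = file.path(out_dir, paste0(basename, "_textile.arff")),
    imu = file.path(out_dir, paste0(basename, "_imu.arff"))
  )
  for (set in names(paths)) {
    chans <- recording_channels(rec, set)
    df <- as.data.frame(rec[, c("time", chans)])
    df$class <- factor(as.character(rec$phase),
                       levels = gait_phases(model_only = TRUE))
    write_gait_arff(df, paths[[set]],
                    relation = paste0("gait_", set))
  }
  invisible(paths)
}
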