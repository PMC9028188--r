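#' Segment a labeled recording into fixed-length windows
#'
#' Slides a window over each contiguous run of samples (runs break wherever
#' timestamps jump by more than 1.5 sampling intervals, e.g. where NC or
#' invalid samples were removed). Each window is labeled with the majority
#' phase inside it; windows whose majority class covers less than
#' `majority` of the samples, ties, and windows whose majority is `NC` are
#' discarded, so boundary-ambiguous instances never enter training.
#'
#' @param rec A labeled (ideally preprocessed) recording.
#' @param window_length Window length in samples. The default of 20 samples
#'   (0.2 s at 100 Hz) keeps the window shorter than a double-support episode
#'   (0.21 s under the default gait schedule), so all three classes can win a
#'   majority.
#' @param stride Step between window starts, in samples.
#' @param majority Minimum fraction the majority class must reach.
#' @param channels Channel columns to keep (default: all).
#' @param recording_id Identifier stored with each instance.
#' @return A `gait_instances` tibble with columns `window` (list of
#'   `window_length` x channels matrices), `label`, `start_time`,
#'   `recording_id`.
#' @export
segment_windows <- function(rec, window_length = 20, stride = 10,
                            majority = 0.6, channels = NULL,
                            recording_id = "rec1") {
  if (!"phase" %in% names(rec)) stopf("recording has no `phase` column")
  if (nrow(rec) < window_length) {
    stopf("window length (%d) exceeds recording length (%d)",
          window_length, nrow(rec))
  }
  if (is.null(channels)) channels <- recording_channels(rec)
  rate <- attr(rec, "sensor_rate")
  if (is.null(rate) || is.na(rate)) rate <- 1 / median(diff(rec$time))

  gap <- c(FALSE, diff(rec$time) > 1.5 / rate)
  run_id <- cumsum(gap)
  mat <- as.matrix(rec[, channels, drop = FALSE])
  phases <- as.character(rec$phase)

  windows <- list()
  labels <- character(0)
  starts <- numeric(0)
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < window_length) next
    for (s in seq(1, length(idx) - window_length + 1, by = stride)) {
      w <- idx[s:(s + window_length - 1)]
      tab <- table(phases[w])
      top <- max(tab)
      if (top / window_length < majority) next
      if (sum(tab == top) > 1) next
      lab <- names(tab)[which.max(tab)]
      if (lab == "NC") next
      windows[[length(windows) + 1]] <- mat[w, , drop = FALSE]
      labels <- c(labels, lab)
      starts <- c(starts, rec$time[w[1]])
    }
  }
  out <- tibble::tibble(
    window = windows,
    label = factor(labels, levels = gait_phases(model_only = TRUE)),
    start_time = starts,
    recording_id = rep(recording_id, length(windows))
  )
  structure(out, class = c("gait_instances", class(out)),
            window_length = as.integer(window_length),
            stride = as.integer(stride),
            channels = channels, sensor_rate = rate)
}

#' Restrict instances to a channel subset
#'
#' @param instances A `gait_instances` tibble.
#' @param channels Channel names to keep.
#' @return The instances with each window reduced to `channels`.
#' @export
instances_channels <- function(instances, channels) {
  out <- instances
  out$window <- lapply(instances$window,
                       function(m) m[, channels, drop = FALSE])
  attr(out, "channels") <- channels
  out
}

# stack instances into an n x (w*c) matrix, channel-major blocks
instances_matrix <- function(instances) {
  w <- attr(instances, "window_length")
  chans <- attr(instances, "channels")
  n <- nrow(instances)
  X <- matrix(0, n, w * length(chans))
  for (i in seq_len(n)) X[i, ] <- as.vector(instances$window[[i]])
  list(X = X, w = w, channels = chans)
}

#' Feature catalog of the extractor
#'
#' @return Character vector of the 22 per-channel statistic names.
#' @export
feature_catalog <- function() {
  c("mean", "variance", "sd", "min", "max", "median", "iqr", "rms",
    "abs_energy", "skewness", "kurtosis", "zero_crossings", "mean_crossings",
    "acf_lag1", "acf_lag2", "acf_lag3", "slope", "dominant_freq",
    "band_0_5", "band_5_10", "band_10_20", "spectral_centroid")
}

#' Extract the time/frequency feature catalog from windowed instances
#'
#' Computes, per channel and instance, 22 documented statistics: moments
#' (mean, variance, standard deviation, skewness, kurtosis), order statistics
#' (min, max, median, interquartile range), energy measures (root mean
#' square, absolute energy), crossing counts (zero and mean crossings),
#' autocorrelation at lags 1-3, the least-squares slope (per sample), and
#' spectral summaries from the discrete Fourier transform of the mean-removed
#' window: dominant frequency (Hz), energy in the bands 0-5, 5-10 and
#' 10-20 Hz, and the spectral centroid. Statistics that are undefined on a
#' window (e.g. the kurtosis of a constant window) are emitted as 0 with one
#' summary warning. Extraction is a pure, deterministic function of each
#' window: row order in equals row order out.
#'
#' @param instances A non-empty `gait_instances`.
#' @param sensor_rate Sampling rate in Hz (taken from the instances when
#'   available).
#' @return A `gait_features` tibble: `label` plus one numeric column per
#'   channel/statistic pair, named `<channel>_<statistic>`.
#' @export
extract_features <- function(instances, sensor_rate = NULL) {
  if (nrow(instances) == 0) stopf("instance set is empty")
  if (is.null(sensor_rate)) sensor_rate <- attr(instances, "sensor_rate")
  if (is.null(sensor_rate)) sensor_rate <- 100
  chans <- attr(instances, "channels")
  w <- attr(instances, "window_length")
  n <- nrow(instances)

  n_undefined <- 0L
  cols <- list(label = instances$label)
  for (ci in seq_along(chans)) {
    M <- vapply(instances$window, function(m) m[, ci], numeric(w))
    M <- matrix(M, nrow = w) # w x n
    fx <- channel_features(M, sensor_rate)
    n_undefined <- n_undefined + attr(fx, "n_undefined")
    colnames(fx) <- paste(chans[ci], colnames(fx), sep = "_")
    for (j in seq_len(ncol(fx))) cols[[colnames(fx)[j]]] <- fx[, j]
  }
  if (n_undefined > 0) {
    warnf("%d undefined feature values (degenerate windows) set to 0",
          n_undefined)
  }
  out <- tibble::as_tibble(cols)
  structure(out, class = c("gait_features", class(out)),
            feature_names = setdiff(names(out), "label"))
}

# 22 statistics for one channel; M is a (window x instances) matrix
channel_features <- function(M, rate) {
  w <- nrow(M)
  n <- ncol(M)
  mu <- colMeans(M)
  centered <- sweep(M, 2, mu)
  ss <- colSums(centered^2)
  v <- ss / (w - 1)
  s <- sqrt(v)

  tt <- seq_len(w) - (w + 1) / 2
  slope <- colSums(tt * M) / sum(tt^2)

  acf_lag <- function(k) {
    num <- colSums(centered[1:(w - k), , drop = FALSE] *
                     centered[(k + 1):w, , drop = FALSE])
    ifelse(ss > 0, num / ss, NA_real_)
  }

  zc <- colSums(M[-1, , drop = FALSE] * M[-w, , drop = FALSE] < 0)
  mc <- colSums(centered[-1, , drop = FALSE] *
                  centered[-w, , drop = FALSE] < 0)

  # spectrum of the mean-removed window
  sp <- stats::mvfft(centered)
  nb <- floor(w / 2)
  freqs <- (seq_len(nb)) * rate / w
  P <- abs(sp[2:(nb + 1), , drop = FALSE])^2 # skip DC (zero after centering)
  ptot <- colSums(P)
  dom <- freqs[apply(P, 2, which.max)]
  dom[ptot == 0] <- 0
  band <- function(lo, hi) {
    sel <- freqs >= lo & freqs < hi
    if (!any(sel)) return(rep(0, n))
    colSums(P[sel, , drop = FALSE])
  }
  centroid <- ifelse(ptot > 0, colSums(freqs * P) / ptot, NA_real_)

  out <- cbind(
    mean = mu, variance = v, sd = s,
    min = apply(M, 2, min), max = apply(M, 2, max),
    median = apply(M, 2, median),
    iqr = apply(M, 2, IQR),
    rms = sqrt(colSums(M^2) / w),
    abs_energy = colSums(M^2),
    skewness = apply(M, 2, e1071::skewness),
    kurtosis = apply(M, 2, e1071::kurtosis),
    zero_crossings = zc, mean_crossings = mc,
    acf_lag1 = acf_lag(1), acf_lag2 = acf_lag(2), acf_lag3 = acf_lag(3),
    slope = slope, dominant_freq = dom,
    band_0_5 = band(0, 5), band_5_10 = band(5, 10),
    band_10_20 = band(10, 20),
    spectral_centroid = centroid
  )
  bad <- !is.finite(out)
  out[bad] <- 0
  attr(out, "n_undefined") <- sum(bad)
  out
}

#' Relevance selection with false-discovery-rate control
#'
#' Tests each feature for association with the class: for every class a
#' one-vs-rest two-sample Wilcoxon rank-sum test (no normality assumption),
#' the feature's p-value being the minimum across classes with a Bonferroni
#' correction for the number of classes. Features are kept iff significant
#' under Benjamini-Yekutieli false-discovery control at `fdr_level` across
#' features; Benjamini-Yekutieli is valid under the arbitrary dependence that
#' strongly correlated feature columns exhibit.
#'
#' @param table A `gait_features` table with >= 2 classes present.
#' @param fdr_level Target false-discovery rate.
#' @return The table restricted to selected feature columns (plus `label`),
#'   with the full test report in the `selection_report` attribute (see
#'   [selection_report()]).
#' @export
select_relevant <- function(table, fdr_level = 0.05) {
  feats <- setdiff(names(table), "label")
  classes <- unique(as.character(table$label))
  if (length(classes) < 2) {
    stopf("relevance selection needs >= 2 classes, got %d", length(classes))
  }
  p <- vapply(feats, function(f) {
    x <- table[[f]]
    pc <- vapply(classes, function(cl) {
      a <- x[table$label == cl]
      b <- x[table$label != cl]
      if (length(unique(c(a, b))) == 1) return(1)
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }, numeric(1))
    min(1, min(pc, na.rm = TRUE) * length(classes))
  }, numeric(1))
  padj <- p.adjust(p, method = "BY")
  kept <- padj <= fdr_level
  report <- tibble::tibble(feature = feats, p_value = unname(p),
                           p_adjusted = unname(padj), kept = unname(kept))
  out <- table[, c("label", feats[kept]), drop = FALSE]
  attr(out, "selection_report") <- report
  attr(out, "feature_names") <- feats[kept]
  class(out) <- unique(c("gait_features", class(out)))
  out
}

#' Feature-selection report
#'
#' @param table A table returned by [select_relevant()].
#' @return Tibble with columns `feature`, `p_value`, `p_adjusted`, `kept`.
#' @export
selection_report <- function(table) {
  attr(table, "selection_report") %||%
    stopf("no selection report attached; run select_relevant() first")
}
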