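#' Read and write pipeline text formats
#'
#' All intermediate streams round-trip through tab-separated UTF-8 text:
#' keypoint tracks (`time`, `landmark`, `x`, `y`, `visibility`), sensor
#' recordings (`time`, one column per channel, `valid`), label streams (one
#' `time<TAB>phase` line per event, `#` comments tolerated) and ground-truth
#' timelines (`time`, `phase`). Malformed rows abort with the offending line
#' number.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return tibbles of the corresponding class; writers return
#'   `path` invisibly.
#' @name gait_io
NULL

check_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    # problems() rows count the header line, i.e. they are file line numbers
    stopf("malformed line %d in '%s': expected %s", pr$row[1], path,
          pr$expected[1])
  }
  df
}

#' @rdname gait_io
#' @export
write_track <- function(x, path) {
  readr::write_tsv(as.data.frame(x)[, c("time", "landmark", "x", "y",
                                        "visibility")], path)
  invisible(path)
}

#' @param camera_rate Frame rate recorded on the returned track.
#' @rdname gait_io
#' @export
read_track <- function(path, camera_rate = NULL) {
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    time = readr::col_double(), landmark = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(),
    visibility = readr::col_double())))
  df <- check_problems(df, path)
  if (is.null(camera_rate)) {
    frames <- sort(unique(df$time))
    camera_rate <- if (length(frames) > 1) 1 / median(diff(frames)) else NA
  }
  structure(df, class = c("gait_track", class(df)), camera_rate = camera_rate)
}

#' @rdname gait_io
#' @export
write_recording <- function(x, path) {
  cols <- c("time", recording_channels(x), intersect("valid", names(x)),
            intersect("phase", names(x)))
  readr::write_tsv(as.data.frame(x)[, cols], path)
  invisible(path)
}

#' @param sensor_rate Sampling rate recorded on the returned recording.
#' @rdname gait_io
#' @export
read_recording <- function(path, sensor_rate = NULL) {
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    time = readr::col_double(), valid = readr::col_logical(),
    phase = readr::col_character(), .default = readr::col_double())))
  df <- check_problems(df, path)
  if (!"time" %in% names(df)) stopf("'%s' has no time column", path)
  chans <- setdiff(names(df), c("time", "valid", "phase"))
  tex <- grep("^textile", chans, value = TRUE)
  if (is.null(sensor_rate)) {
    sensor_rate <- if (nrow(df) > 1) 1 / median(diff(df$time)) else NA
  }
  cls <- c("gait_recording", class(df))
  if ("phase" %in% names(df)) {
    df$phase <- phase_factor(df$phase)
    cls <- c("gait_labeled_recording", cls)
  }
  structure(df, class = cls, sensor_rate = sensor_rate,
            textile_channels = tex, imu_channels = setdiff(chans, tex))
}

#' @rdname gait_io
#' @export
write_labels <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# gait label stream: time<TAB>phase", con)
  writeLines(sprintf("%.6f\t%s", x$time, as.character(x$phase)), con)
  invisible(path)
}

#' @rdname gait_io
#' @export
read_labels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) {
    stopf("malformed line %d in '%s': expected 'time<TAB>phase'",
          rows[bad[1]], path)
  }
  time <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  phase <- vapply(parts, `[[`, "", 2)
  if (anyNA(time)) {
    stopf("malformed line %d in '%s': non-numeric timestamp",
          rows[which(is.na(time))[1]], path)
  }
  unknown <- !phase %in% gait_phases()
  if (any(unknown)) {
    stopf("malformed line %d in '%s': unknown label '%s'",
          rows[which(unknown)[1]], path, phase[which(unknown)[1]])
  }
  out <- tibble::tibble(time = time, phase = phase_factor(phase))
  structure(out, class = c("gait_labels", class(out)))
}

#' @rdname gait_io
#' @export
write_timeline <- function(x, path) {
  readr::write_tsv(data.frame(time = x$time, phase = as.character(x$phase)),
                   path)
  invisible(path)
}

#' @rdname gait_io
#' @export
read_timeline <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    time = readr::col_double(), phase = readr::col_character())))
  df <- check_problems(df, path)
  unknown <- !df$phase %in% gait_phases()
  if (any(unknown)) {
    stopf("malformed line %d in '%s': unknown phase '%s'",
          which(unknown)[1] + 1L, path, df$phase[which(unknown)[1]])
  }
  out <- tibble::tibble(time = df$time, phase = phase_factor(df$phase))
  rate <- if (nrow(out) > 1) 1 / median(diff(out$time)) else NA
  structure(out, class = c("gait_timeline", class(out)), sensor_rate = rate)
}
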