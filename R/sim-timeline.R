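#' Simulate a ground-truth gait-phase timeline
#'
#' Builds the per-sample ground truth for one trial at the sensor rate. The
#' participant stands at the middle of the path until `walk_onset`, then
#' walks back and forth at `walking_speed`, pausing `turnaround_time` seconds
#' at each end. While walking, the cycle repeats the schedule
#' double support -> left swing -> double support -> right swing, so a
#' double-support interval always separates the two single-support phases.
#' Samples whose body-center position falls inside the horizontal
#' `nc_margin_fraction` of the image are overridden to `NC`.
#'
#' @param config A [gait_sim_config()].
#' @return A `gait_timeline` tibble with columns `time` (s, true clock),
#'   `phase` (the ground-truth label including `NC`), `cycle_phase` (the
#'   underlying gait phase ignoring the NC override), `body_s` (body-center
#'   position along the path, m), `body_x` (normalized image x) and
#'   `direction` (walking direction, -1/0/+1).
#' @export
#' @examples
#' tl <- simulate_phase_timeline(gait_sim_config(duration = 20))
#' table(tl$phase)
simulate_phase_timeline <- function(config) {
  validate_sim_config(config)
  if (config$duration <= 0) {
    return(empty_timeline(config))
  }
  time <- seq(0, config$duration - 1 / config$sensor_rate,
              by = 1 / config$sensor_rate)

  traj <- body_trajectory(time, config)
  cycle_phase <- cycle_schedule(time, config)

  phase <- cycle_phase
  if (config$nc_margin_fraction > 0) {
    nc <- traj$body_x < config$nc_margin_fraction |
      traj$body_x > 1 - config$nc_margin_fraction
    phase[nc] <- "NC"
  }

  out <- tibble::tibble(
    time = time,
    phase = phase_factor(phase),
    cycle_phase = phase_factor(cycle_phase),
    body_s = traj$body_s,
    body_x = traj$body_x,
    direction = traj$direction
  )
  new_timeline(out, config)
}

empty_timeline <- function(config) {
  out <- tibble::tibble(
    time = numeric(0), phase = phase_factor(character(0)),
    cycle_phase = phase_factor(character(0)), body_s = numeric(0),
    body_x = numeric(0), direction = numeric(0)
  )
  new_timeline(out, config)
}

new_timeline <- function(df, config) {
  structure(df, class = c("gait_timeline", class(df)),
            sensor_rate = config$sensor_rate, sim_config = config)
}

# Piecewise-linear back-and-forth body trajectory: stand at mid-path until
# walk_onset, then alternate full traversals with turnaround pauses.
body_trajectory <- function(time, config) {
  L <- config$path_length
  v <- config$walking_speed
  dwell <- config$turnaround_time
  horizon <- max(time, config$duration)

  # segments: (t0, t1, s0, s1)
  seg <- list(c(0, config$walk_onset, L / 2, L / 2))
  t <- config$walk_onset
  s <- L / 2
  target <- L
  while (t < horizon) {
    dt <- abs(target - s) / v
    seg[[length(seg) + 1]] <- c(t, t + dt, s, target)
    t <- t + dt
    s <- target
    seg[[length(seg) + 1]] <- c(t, t + dwell, s, s)
    t <- t + dwell
    target <- if (target == L) 0 else L
  }
  segm <- do.call(rbind, seg)
  idx <- pmax(1, findInterval(time, segm[, 1]))
  t0 <- segm[idx, 1]; t1 <- segm[idx, 2]
  s0 <- segm[idx, 3]; s1 <- segm[idx, 4]
  frac <- ifelse(t1 > t0, pmin(1, pmax(0, (time - t0) / (t1 - t0))), 0)
  body_s <- s0 + frac * (s1 - s0)
  direction <- sign(s1 - s0)
  # during pauses keep the direction the walker is about to take
  for (i in seq_along(direction)) {
    if (direction[i] == 0 && i > 1) direction[i] <- direction[i - 1]
  }
  if (length(direction) && direction[1] == 0) {
    nz <- which(direction != 0)
    direction[1] <- if (length(nz)) direction[nz[1]] else 0
    direction <- cummax_dir(direction)
  }
  list(body_s = body_s, body_x = path_to_image_x(body_s, L),
       direction = direction)
}

cummax_dir <- function(d) {
  # carry the first nonzero direction backward over the leading zeros
  nz <- which(d != 0)
  if (length(nz) && nz[1] > 1) d[seq_len(nz[1] - 1)] <- d[nz[1]]
  d
}

# Phase of the gait cycle at each time point (ignoring NC). Before walking
# onset both feet are on the ground.
cycle_schedule <- function(time, config) {
  ds <- config$double_support_fraction
  sw <- 1 - config$stance_fraction
  p <- c(ds, sw, ds, sw)
  p <- p / sum(p)
  cuts <- cumsum(p)

  u <- ((time - config$walk_onset) %% config$stride_period) /
    config$stride_period
  phase <- rep("RSTLST", length(time))
  walking <- time >= config$walk_onset
  phase[walking & u >= cuts[1] & u < cuts[2]] <- "RSTLSW"
  phase[walking & u >= cuts[3]] <- "RSWLST"
  phase
}

# swing intervals (start, end in seconds) for one foot, derived from the
# run-length structure of the cycle phases
swing_segments <- function(timeline, foot = c("right", "left")) {
  foot <- match.arg(foot)
  target <- if (foot == "right") "RSWLST" else "RSTLSW"
  cp <- as.character(timeline$cycle_phase)
  r <- rle(cp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values == target
  dt <- 1 / attr(timeline, "sensor_rate")
  data.frame(
    t_start = timeline$time[starts[keep]],
    t_end = timeline$time[ends[keep]] + dt
  )
}

#' @export
print.gait_timeline <- function(x, ...) {
  cat(sprintf("<gait_timeline> %d samples at %g Hz\n",
              nrow(x), attr(x, "sensor_rate")))
  if (nrow(x)) print(table(phase = x$phase))
  invisible(x)
}
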