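#' Configuration for the synthetic gait trial simulator
#'
#' Defines one simulated walking trial: a participant stands at the middle of
#' a straight path, performs three short synchronization jumps, then walks
#' back and forth at a slow, steady pace with brief turnarounds at the path
#' ends. Defaults reproduce the study protocol the pipeline is designed for:
#' a 3.5 m path, 0.7 m/s pace, 100 Hz sensor sampling, a 60 frames/s camera,
#' 10 textile pressure channels and 9 IMU channels.
#'
#' Gait proportions default to slow-gait values consistent with the 0.7 m/s
#' pace: stride period 1.4 s, stance 65% of the cycle and double support 15%
#' of the cycle per transition, so each double-support episode lasts 0.21 s.
#' The cycle satisfies `stance_fraction = 0.5 + double_support_fraction`, the
#' consistency condition for a symmetric two-legged schedule.
#'
#' @param duration Trial length in seconds.
#' @param sensor_rate Acquisition sampling rate in Hz.
#' @param camera_rate Camera frame rate in frames/s.
#' @param stride_period Full gait-cycle duration in seconds.
#' @param stance_fraction Fraction of the cycle each foot is on the ground.
#' @param double_support_fraction Fraction of the cycle spent in double
#'   support at each of the two step transitions (total double support is
#'   twice this value).
#' @param path_length Walking path length in meters.
#' @param walking_speed Nominal walking speed in m/s.
#' @param nc_margin_fraction Horizontal image margin (fraction of frame
#'   width) inside which samples are marked `NC`; 0 disables NC zones.
#' @param turnaround_time Pause at each path end, in seconds.
#' @param n_textile_channels,n_imu_channels Channel counts.
#' @param gain_spread Log-scale spread of the per-channel textile gains
#'   (log-normal, median 1); models sensitivity variability between
#'   hand-made resistive sensors.
#' @param noise_sd White-noise standard deviation on the textile channels
#'   (signal units); IMU noise scales proportionally.
#' @param keypoint_noise_sd Positional jitter of the pose landmarks, in
#'   normalized image units.
#' @param drift_rate Magnitude of the slow baseline drift, units per sqrt(s).
#' @param recovery_time_constant Time constant (s) of the drift recovery,
#'   matching the sensors' pressure-release recovery behaviour.
#' @param dropout_rate Per-sample probability of a transmission dropout
#'   (sample flagged invalid, channel values missing).
#' @param outlier_rate Per-sample, per-channel probability of a spike
#'   outlier.
#' @param jump_times Times (s) of the pre-trial synchronization jumps; must
#'   precede `walk_onset`.
#' @param walk_onset Time (s) walking begins; defaults to 2 s after the last
#'   jump (or 0 with no jumps).
#' @param camera_clock_offset,sensor_clock_offset Clock offsets (s) added to
#'   the camera and acquisition timestamps, so the synchronization stage has
#'   a real misalignment to recover.
#' @param occlusion_rate Expected occlusion episodes per second degrading
#'   visibility of the camera-far (left) leg; 0 disables occlusions.
#' @param rng_seed Integer seed; identical configurations produce identical
#'   simulations.
#' @return A `gait_sim_config` list.
#' @export
#' @examples
#' cfg <- gait_sim_config(duration = 30, rng_seed = 1)
#' cfg$stride_period
gait_sim_config <- function(duration = 60,
                            sensor_rate = 100,
                            camera_rate = 60,
                            stride_period = 1.4,
                            stance_fraction = 0.65,
                            double_support_fraction = 0.15,
                            path_length = 3.5,
                            walking_speed = 0.7,
                            nc_margin_fraction = 0.15,
                            turnaround_time = 1,
                            n_textile_channels = 10,
                            n_imu_channels = 9,
                            gain_spread = 0.4,
                            noise_sd = 0.05,
                            keypoint_noise_sd = 5e-4,
                            drift_rate = 0.02,
                            recovery_time_constant = 17,
                            dropout_rate = 0.002,
                            outlier_rate = 0.001,
                            jump_times = c(2, 3, 4),
                            walk_onset = NULL,
                            camera_clock_offset = 0,
                            sensor_clock_offset = 0,
                            occlusion_rate = 0,
                            rng_seed = 1L) {
  if (is.null(walk_onset)) {
    walk_onset <- if (length(jump_times)) max(jump_times) + 2 else 0
  }
  cfg <- list(
    duration = duration, sensor_rate = sensor_rate, camera_rate = camera_rate,
    stride_period = stride_period, stance_fraction = stance_fraction,
    double_support_fraction = double_support_fraction,
    path_length = path_length, walking_speed = walking_speed,
    nc_margin_fraction = nc_margin_fraction, turnaround_time = turnaround_time,
    n_textile_channels = n_textile_channels, n_imu_channels = n_imu_channels,
    gain_spread = gain_spread, noise_sd = noise_sd,
    keypoint_noise_sd = keypoint_noise_sd, drift_rate = drift_rate,
    recovery_time_constant = recovery_time_constant,
    dropout_rate = dropout_rate, outlier_rate = outlier_rate,
    jump_times = jump_times, walk_onset = walk_onset,
    camera_clock_offset = camera_clock_offset,
    sensor_clock_offset = sensor_clock_offset,
    occlusion_rate = occlusion_rate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "gait_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$duration < 0) stopf("`duration` must be >= 0, got %s", cfg$duration)
  for (f in c("sensor_rate", "camera_rate", "stride_period", "path_length",
              "walking_speed")) {
    if (cfg[[f]] <= 0) stopf("`%s` must be > 0", f)
  }
  if (!(cfg$stance_fraction > 0 && cfg$stance_fraction < 1)) {
    stopf("`stance_fraction` must lie in (0, 1)")
  }
  if (!(cfg$double_support_fraction > 0 &&
        2 * cfg$double_support_fraction <= cfg$stance_fraction)) {
    stopf(paste0("inconsistent gait fractions: need ",
                 "2 * double_support_fraction <= stance_fraction < 1"))
  }
  if (cfg$nc_margin_fraction < 0 || cfg$nc_margin_fraction >= 0.5) {
    stopf("`nc_margin_fraction` must lie in [0, 0.5)")
  }
  for (f in c("gain_spread", "noise_sd", "keypoint_noise_sd", "drift_rate",
              "dropout_rate", "outlier_rate", "occlusion_rate")) {
    if (cfg[[f]] < 0) stopf("`%s` must be >= 0", f)
  }
  if (length(cfg$jump_times) && any(cfg$jump_times >= cfg$walk_onset)) {
    stopf("`jump_times` must all precede `walk_onset` (%.2f s)", cfg$walk_onset)
  }
  invisible(cfg)
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat("<gait_sim_config>\n")
  cat(sprintf("  duration %.1f s | sensor %g Hz | camera %g fps | seed %d\n",
              x$duration, x$sensor_rate, x$camera_rate, x$rng_seed))
  cat(sprintf("  stride %.2f s, stance %.0f%%, double support 2 x %.0f%%\n",
              x$stride_period, 100 * x$stance_fraction,
              100 * x$double_support_fraction))
  cat(sprintf("  path %.1f m at %.2f m/s, NC margin %.0f%%, %d jumps\n",
              x$path_length, x$walking_speed, 100 * x$nc_margin_fraction,
              length(x$jump_times)))
  invisible(x)
}

# horizontal span of the walking path in normalized image coordinates
path_image_span <- function() c(0.07, 0.93)

# meters of path per normalized image unit, for a given path length
default_pixel_to_meter <- function(path_length = 3.5) {
  span <- path_image_span()
  path_length / (span[2] - span[1])
}

path_to_image_x <- function(s, path_length) {
  span <- path_image_span()
  span[1] + (span[2] - span[1]) * s / path_length
}
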