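#' Simulate a multichannel sensor recording for a trial
#'
#' Generates the 100 Hz acquisition stream: textile pressure channels and IMU
#' channels keyed to the ground-truth gait phases. Each textile channel is a
#' smoothed, phase-keyed loading waveform (high while the channel's leg bears
#' weight) multiplied by a per-channel log-normal gain (median 1, log-scale
#' spread `gain_spread`, modelling the sensitivity variability of hand-made
#' resistive sensors), plus a slow drift with recovery time constant
#' `recovery_time_constant`, white noise, spike outliers, and transmission
#' dropouts flagged in the `valid` column. IMU channels carry phase-keyed
#' acceleration and angular-rate patterns (vertical impacts at each foot
#' strike, swing-side-signed thigh angular velocity, heading-dependent
#' magnetometer) and large acceleration spikes at the synchronization jumps.
#'
#' @param timeline A non-empty [simulate_phase_timeline()] result.
#' @param config The same [gait_sim_config()] used for the timeline.
#' @return A `gait_recording` tibble: `time` (s, acquisition clock), one
#'   column per channel, and `valid` (logical). Channel names are stored in
#'   attributes `textile_channels` and `imu_channels`.
#' @export
#' @examples
#' cfg <- gait_sim_config(duration = 12)
#' rec <- simulate_sensors(simulate_phase_timeline(cfg), cfg)
#' names(rec)
simulate_sensors <- function(timeline, config) {
  validate_sim_config(config)
  if (nrow(timeline) == 0) stopf("timeline is empty; nothing to simulate")
  if (config$n_imu_channels > 9) {
    stopf("at most 9 IMU channels are supported (3x acc, 3x gyro, 3x mag)")
  }

  with_seed_(child_seed(config$rng_seed, "sensors"), {
    t <- timeline$time
    n <- length(t)
    dt <- 1 / config$sensor_rate
    walking <- t >= config$walk_onset
    u <- ((t - config$walk_onset) %% config$stride_period) /
      config$stride_period
    cp <- as.character(timeline$cycle_phase)
    jump <- jump_y_bump(t, config$jump_times, amp = 1, width = 0.05)

    ntex <- config$n_textile_channels
    side <- rep(c("right", "left"), length.out = ntex)
    gains <- rlnorm(ntex, meanlog = 0, sdlog = config$gain_spread)

    load_right <- smooth_exp(ifelse(cp == "RSWLST", 0.15, 1), dt, 0.06)
    load_left <- smooth_exp(ifelse(cp == "RSTLSW", 0.15, 1), dt, 0.06)

    textile <- matrix(0, n, ntex)
    for (i in seq_len(ntex)) {
      phi <- 2 * pi * ((i - 1) %/% 2) / max(1, ceiling(ntex / 2))
      base <- if (side[i] == "right") load_right else load_left
      shape <- 0.3 * sin(2 * pi * u + phi) * walking
      x <- gains[i] * (base + shape + 1.5 * jump)
      x <- x + ou_drift(n, dt, config$recovery_time_constant,
                        config$drift_rate)
      if (config$noise_sd > 0) x <- x + rnorm(n, sd = config$noise_sd)
      if (config$outlier_rate > 0) {
        hit <- which(runif(n) < config$outlier_rate)
        if (length(hit)) {
          x[hit] <- x[hit] + sample(c(-1, 1), length(hit), TRUE) *
            (6 + stats::rexp(length(hit), 1))
        }
      }
      textile[, i] <- x
    }
    colnames(textile) <- sprintf("textile_%02d", seq_len(ntex))

    imu <- imu_channels(timeline, config, t, u, walking, jump, dt)
    imu <- imu[, seq_len(config$n_imu_channels), drop = FALSE]

    valid <- rep(TRUE, n)
    if (config$dropout_rate > 0) {
      valid <- runif(n) >= config$dropout_rate
      textile[!valid, ] <- NA_real_
      imu[!valid, ] <- NA_real_
    }

    out <- tibble::as_tibble(cbind(
      data.frame(time = t + config$sensor_clock_offset),
      as.data.frame(textile), as.data.frame(imu)
    ))
    out$valid <- valid
    structure(out, class = c("gait_recording", class(out)),
              sensor_rate = config$sensor_rate,
              textile_channels = colnames(textile),
              imu_channels = colnames(imu),
              n_dropouts = sum(!valid),
              sim_config = config)
  })
}

# first-order exponential smoothing with time constant tau (seconds)
smooth_exp <- function(x, dt, tau) {
  a <- dt / (tau + dt)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive",
                           init = x[1]))
}

# Ornstein-Uhlenbeck baseline drift: random loading that relaxes with the
# sensors' recovery time constant
ou_drift <- function(n, dt, tau, rate) {
  if (rate <= 0) return(rep(0, n))
  decay <- exp(-dt / tau)
  eps <- rnorm(n, sd = rate * sqrt(dt))
  as.numeric(stats::filter(eps, decay, method = "recursive"))
}

imu_channels <- function(timeline, config, t, u, walking, jump, dt) {
  n <- length(t)
  cp <- as.character(timeline$cycle_phase)
  swing_sign <- smooth_exp(
    ifelse(cp == "RSWLST", 1, ifelse(cp == "RSTLSW", -1, 0)), dt, 0.05)

  # vertical impacts at every transition into double support (foot strike)
  strike <- c(FALSE, cp[-1] == "RSTLST" & cp[-n] != "RSTLST") & walking
  impact <- smooth_exp(as.numeric(strike) * 6, dt, 0.03)

  turning <- walking & abs(diff(c(timeline$body_s[1], timeline$body_s))) < 1e-12
  noise <- config$noise_sd

  acc_x <- 1.0 * sin(4 * pi * u) * walking + rnorm(n, sd = 6 * noise)
  acc_y <- 0.5 * sin(2 * pi * u) * walking + rnorm(n, sd = 6 * noise)
  acc_z <- 9.81 + impact + 15 * jump + rnorm(n, sd = 6 * noise)
  gyro_x <- 0.3 * sin(2 * pi * u + 1) * walking + rnorm(n, sd = noise)
  gyro_y <- 2 * swing_sign + rnorm(n, sd = noise)
  gyro_z <- 1.5 * as.numeric(turning) * timeline$direction +
    rnorm(n, sd = noise)
  mag_x <- 25 * timeline$direction + rnorm(n, sd = 10 * noise)
  mag_y <- 10 + rnorm(n, sd = 10 * noise)
  mag_z <- -40 + rnorm(n, sd = 10 * noise)

  cbind(acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
        gyro_x = gyro_x, gyro_y = gyro_y, gyro_z = gyro_z,
        mag_x = mag_x, mag_y = mag_y, mag_z = mag_z)
}

#' Channel names of a recording
#'
#' @param rec A `gait_recording`.
#' @param which `"all"`, `"textile"` or `"imu"`.
#' @return Character vector of channel column names.
#' @export
recording_channels <- function(rec, which = c("all", "textile", "imu")) {
  which <- match.arg(which)
  tex <- attr(rec, "textile_channels")
  imu <- attr(rec, "imu_channels")
  if (is.null(tex) && is.null(imu)) {
    chans <- setdiff(names(rec), c("time", "valid", "phase"))
    tex <- grep("^textile", chans, value = TRUE)
    imu <- setdiff(chans, tex)
  }
  switch(which, all = c(tex, imu), textile = tex, imu = imu)
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d samples, %d channels at %g Hz (%d invalid)\n",
              nrow(x), length(recording_channels(x)),
              attr(x, "sensor_rate") %||% NA,
              sum(!x$valid)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
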