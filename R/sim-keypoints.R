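#' Simulate a pose keypoint track for a trial
#'
#' Emulates the per-frame output of a full-body pose model watching the
#' walking trial from the side: 33 landmarks in normalized image coordinates
#' (origin top-left, y increasing downward). Heel and toe landmarks of a foot
#' are stationary during that foot's stance and translate forward during its
#' swing with a smooth trapezoidal velocity profile; the body center follows
#' the back-and-forth traversal; both feet (and the rest of the body) show a
#' transient vertical displacement at every synchronization jump. Landmark
#' positions carry i.i.d. jitter of `keypoint_noise_sd` image units.
#'
#' @param timeline A non-empty [simulate_phase_timeline()] result.
#' @param config The same [gait_sim_config()] used for the timeline.
#' @return A `gait_track` tibble with columns `time` (s, camera clock),
#'   `landmark`, `x`, `y`, `visibility`.
#' @export
#' @examples
#' cfg <- gait_sim_config(duration = 12)
#' trk <- simulate_keypoints(simulate_phase_timeline(cfg), cfg)
#' dplyr::count(trk, landmark)
simulate_keypoints <- function(timeline, config) {
  validate_sim_config(config)
  if (nrow(timeline) == 0) stopf("timeline is empty; nothing to simulate")

  with_seed_(child_seed(config$rng_seed, "keypoints"), {
    t_true <- seq(0, config$duration - 1 / config$camera_rate,
                  by = 1 / config$camera_rate)
    n <- length(t_true)
    L <- config$path_length
    img_per_m <- diff(path_image_span()) / L

    body_s <- approx(timeline$time, timeline$body_s, xout = t_true,
                     rule = 2)$y
    direction <- approx(timeline$time, timeline$direction, xout = t_true,
                        method = "constant", rule = 2)$y

    feet <- lapply(c("right", "left"), function(foot) {
      foot_motion(timeline, config, t_true, body_s, direction, foot)
    })
    names(feet) <- c("right", "left")

    jump_bump <- jump_y_bump(t_true, config$jump_times)

    lm <- gait_landmarks()
    X <- matrix(NA_real_, n, length(lm), dimnames = list(NULL, lm))
    Y <- matrix(NA_real_, n, length(lm), dimnames = list(NULL, lm))

    tpl <- landmark_template()
    body_x_img <- path_to_image_x(body_s, L)
    for (i in seq_len(nrow(tpl))) {
      nm <- tpl$landmark[i]
      if (nm %in% foot_landmarks()) next
      X[, nm] <- body_x_img + tpl$dx[i] * img_per_m * direction
      Y[, nm] <- tpl$y[i] - jump_bump
    }

    ground_y <- 0.85
    for (side in c("right", "left")) {
      f <- feet[[side]]
      heel_x <- path_to_image_x(f$s, L)
      toe_x <- path_to_image_x(pmin(pmax(f$s + 0.18 * direction, 0), L), L)
      lift <- 0.04 * sin(pi * f$u)
      X[, paste0(side, "_heel")] <- heel_x
      Y[, paste0(side, "_heel")] <- ground_y - lift - jump_bump
      X[, paste0(side, "_foot_index")] <- toe_x
      Y[, paste0(side, "_foot_index")] <- ground_y + 0.02 - 0.8 * lift -
        jump_bump
      X[, paste0(side, "_ankle")] <- heel_x
      Y[, paste0(side, "_ankle")] <- ground_y - 0.03 - lift - jump_bump
    }

    if (config$keypoint_noise_sd > 0) {
      X <- X + rnorm(length(X), sd = config$keypoint_noise_sd)
      Y <- Y + rnorm(length(Y), sd = config$keypoint_noise_sd)
    }
    X[] <- pmin(pmax(X, 0), 1)
    Y[] <- pmin(pmax(Y, 0), 1)

    V <- matrix(1, n, length(lm), dimnames = list(NULL, lm))
    if (config$occlusion_rate > 0) {
      n_ep <- stats::rpois(1, config$occlusion_rate * config$duration)
      far_leg <- c("left_knee", "left_ankle", "left_heel", "left_foot_index")
      if (n_ep > 0) {
        starts <- runif(n_ep, 0, config$duration)
        for (st in starts) {
          sel <- t_true >= st & t_true < st + 0.8
          V[sel, far_leg] <- 0.3
        }
      }
    }

    out <- tibble::tibble(
      time = rep(t_true + config$camera_clock_offset, times = length(lm)),
      landmark = rep(lm, each = n),
      x = as.vector(X),
      y = as.vector(Y),
      visibility = as.vector(V)
    )
    out <- dplyr::arrange(out, .data$time, .data$landmark)
    structure(out, class = c("gait_track", class(out)),
              camera_rate = config$camera_rate, sim_config = config)
  })
}

# trapezoidal swing velocity profile: fraction of the swing distance covered
# at normalized swing time u, with rise/fall fraction r
swing_progress <- function(u, r = 0.06) {
  u <- pmin(pmax(u, 0), 1)
  area <- 1 - r
  out <- ifelse(
    u < r, (u^2 / (2 * r)) / area,
    ifelse(u <= 1 - r, (u - r / 2) / area,
           1 - ((1 - u)^2 / (2 * r)) / area)
  )
  out
}

# per-frame path position (m) and swing progress u for one foot
foot_motion <- function(timeline, config, t_true, body_s, direction, foot) {
  n <- length(t_true)
  seg <- swing_segments(timeline, foot)
  s <- rep(NA_real_, n)
  u <- rep(0, n)
  cur <- config$path_length / 2
  for (k in seq_len(nrow(seg))) {
    t0 <- seg$t_start[k]; t1 <- seg$t_end[k]
    pre <- which(is.na(s) & t_true < t0)
    s[pre] <- cur
    inside <- which(t_true >= t0 & t_true < t1)
    if (length(inside)) {
      i_end <- min(n, max(inside) + 1)
      dir_end <- direction[i_end]
      target <- body_s[i_end] + 0.35 * dir_end
      target <- min(max(target, 0), config$path_length)
      uu <- (t_true[inside] - t0) / (t1 - t0)
      s[inside] <- cur + swing_progress(uu) * (target - cur)
      u[inside] <- uu
      cur <- target
    }
  }
  s[is.na(s)] <- cur
  list(s = s, u = u)
}

jump_y_bump <- function(t, jump_times, amp = 0.08, width = 0.04) {
  bump <- rep(0, length(t))
  for (tj in jump_times) {
    bump <- bump + amp * exp(-(t - tj)^2 / (2 * width^2))
  }
  bump
}

#' @export
print.gait_track <- function(x, ...) {
  cat(sprintf("<gait_track> %d frames x %d landmarks at %g fps\n",
              length(unique(x$time)), length(unique(x$landmark)),
              attr(x, "camera_rate")))
  invisible(x)
}
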