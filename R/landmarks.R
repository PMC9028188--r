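#' The 33-landmark body schema
#'
#' Names of the 33 body landmarks produced by the pose backend that the
#' labeler consumes. The pipeline itself only relies on the heels, the toes
#' (`*_foot_index`) and the hips (whose mean x-coordinate serves as the body
#' center for the turnaround rule); the remaining landmarks are carried for
#' schema compatibility with full-body pose models.
#'
#' @return Character vector of 33 landmark names.
#' @export
#' @examples
#' length(gait_landmarks())
gait_landmarks <- function() {
  c(
    "nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index"
  )
}

# landmarks the simulator animates explicitly; everything else rides on the
# body center with a fixed template offset
foot_landmarks <- function() {
  c("left_heel", "right_heel", "left_foot_index", "right_foot_index",
    "left_ankle", "right_ankle")
}

# template offsets (x along path in meters, y in normalized image units,
# origin top-left, y increasing downward) for non-foot landmarks
landmark_template <- function() {
  lm <- gait_landmarks()
  tpl <- data.frame(landmark = lm, dx = 0, y = 0.45)
  y_of <- c(
    nose = 0.18, left_eye_inner = 0.17, left_eye = 0.17, left_eye_outer = 0.17,
    right_eye_inner = 0.17, right_eye = 0.17, right_eye_outer = 0.17,
    left_ear = 0.18, right_ear = 0.18, mouth_left = 0.20, mouth_right = 0.20,
    left_shoulder = 0.28, right_shoulder = 0.28,
    left_elbow = 0.40, right_elbow = 0.40,
    left_wrist = 0.50, right_wrist = 0.50,
    left_pinky = 0.52, right_pinky = 0.52,
    left_index = 0.52, right_index = 0.52,
    left_thumb = 0.51, right_thumb = 0.51,
    left_hip = 0.52, right_hip = 0.52,
    left_knee = 0.68, right_knee = 0.68
  )
  idx <- match(names(y_of), tpl$landmark)
  tpl$y[idx] <- unname(y_of)
  tpl$dx[grepl("^left", tpl$landmark)] <- -0.02
  tpl$dx[grepl("^right", tpl$landmark)] <- 0.02
  tpl
}
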