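# Experiment gain, epoch protocol, and reference-frame transforms.
#
# The experiment gain G is the ratio of the animal's displacement in the
# visual-cue frame (landmark or stripe) to its displacement in the
# laboratory frame. A session is divided into four epochs, specified in
# laboratory-frame laps: G = 1 in Epoch 1, a constant-rate linear ramp to
# G_final across Epoch 2, G = G_final through Epochs 3 and 4; cues are
# extinguished in Epoch 4 but gain bookkeeping continues.

#' Gain profile of a session
#'
#' Defines the experiment gain as a piecewise-linear function of
#' laboratory-frame distance run, structured in four epochs.
#'
#' @param epoch_laps Numeric length-4 vector: number of lab-frame laps in
#'   Epochs 1-4. Epoch boundaries are the cumulative sums.
#' @param final_gain Dimensionless gain held through Epochs 3-4 and ramped
#'   to linearly across Epoch 2.
#' @param cue Which cue set this gain governs: `"landmark"` or `"stripe"`.
#' @param landmarks_visible Logical length-4: cue visibility per epoch
#'   (default: visible in Epochs 1-3, off in Epoch 4).
#' @return An object of class `gain_profile` with fields `epoch_laps`,
#'   `epoch_boundaries` (cumulative laps), `final_gain`, `ramp_rate`
#'   (gain change per lab lap in Epoch 2), `cue`, `landmarks_visible`.
#' @export
#' @examples
#' p <- gain_profile(epoch_laps = c(15, 10, 15, 0), final_gain = 1.5)
#' gain_at(p, c(0, 15.5, 30) * 360)
gain_profile <- function(epoch_laps = c(15, 10, 15, 5), final_gain = 1,
                         cue = c("landmark", "stripe"),
                         landmarks_visible = c(TRUE, TRUE, TRUE, FALSE)) {
  cue <- match.arg(cue)
  stopifnot(length(epoch_laps) == 4, all(epoch_laps >= 0),
            length(landmarks_visible) == 4, is.logical(landmarks_visible),
            is.numeric(final_gain), length(final_gain) == 1, final_gain >= 0)
  if (epoch_laps[2] == 0 && final_gain != 1) {
    stop("a zero-length Epoch 2 with final_gain != 1 would make the gain discontinuous")
  }
  structure(list(
    epoch_laps = as.numeric(epoch_laps),
    epoch_boundaries = cumsum(as.numeric(epoch_laps)),
    final_gain = final_gain,
    ramp_rate = if (epoch_laps[2] > 0) (final_gain - 1) / epoch_laps[2] else 0,
    cue = cue,
    landmarks_visible = landmarks_visible
  ), class = "gain_profile")
}

#' @export
print.gain_profile <- function(x, ...) {
  cat("Gain profile (", x$cue, " cue)\n", sep = "")
  cat("  epoch laps:", paste(x$epoch_laps, collapse = ", "),
      " G_final =", x$final_gain, "\n")
  cat("  ramp rate:", signif(x$ramp_rate, 4), "per lab lap;",
      "cue visible:", paste(x$landmarks_visible, collapse = ", "), "\n")
  invisible(x)
}

#' Experiment gain at a laboratory-frame distance
#'
#' @param profile A [gain_profile()].
#' @param lab_distance Unwrapped lab-frame distance run, in degrees
#'   (laps x 360). Must be non-negative.
#' @return Dimensionless gain, vectorized over `lab_distance`. Exactly 1
#'   within Epoch 1, linear in Epoch 2, exactly `final_gain` from the start
#'   of Epoch 3 on.
#' @export
gain_at <- function(profile, lab_distance) {
  stopifnot(inherits(profile, "gain_profile"))
  if (any(lab_distance < 0)) stop("lab_distance must be non-negative")
  laps <- lab_distance / 360
  b <- profile$epoch_boundaries
  g <- rep(1, length(laps))
  in_ramp <- laps > b[1] & laps < b[2]
  g[in_ramp] <- 1 + profile$ramp_rate * (laps[in_ramp] - b[1])
  g[laps >= b[2]] <- profile$final_gain
  g
}

# Antiderivative of the gain over lab distance (degrees): exact for the
# piecewise-linear profile, so frame transforms are closed-form.
gain_integral <- function(profile, lab_distance) {
  if (any(lab_distance < 0)) stop("lab_distance must be non-negative")
  b_deg <- profile$epoch_boundaries * 360
  L2 <- profile$epoch_laps[2] * 360 # ramp length in degrees
  gf <- profile$final_gain
  d <- lab_distance
  out <- numeric(length(d))
  seg1 <- pmin(d, b_deg[1])
  out <- seg1
  x <- pmin(pmax(d - b_deg[1], 0), L2) # progress into ramp
  if (L2 > 0) out <- out + x + (gf - 1) * x^2 / (2 * L2)
  out <- out + gf * pmax(d - b_deg[2], 0)
  out
}

# Which epoch (1..4) a lab distance falls in; distances past the scheduled
# session end stay in epoch 4.
epoch_of <- function(profile, lab_distance) {
  laps <- lab_distance / 360
  pmin(findInterval(laps, profile$epoch_boundaries, left.open = TRUE) + 1L, 4L)
}

#' Transform a trajectory from the laboratory frame to a cue frame
#'
#' Accumulates the cue-frame angle theta_f(t) = theta_f(0) + integral of
#' G d(theta_lab) along the trajectory, using the exact antiderivative of
#' the piecewise-linear gain. When G is identically 1 the result equals the
#' lab angle to machine precision.
#'
#' @param traj An [angular_trajectory()].
#' @param profile A [gain_profile()] governing the target frame.
#' @param frame_origin Cue-frame angle at the first sample; defaults to the
#'   lab angle at the first sample (frames coincide at session start).
#' @return A data frame of class `frame_position` with columns `time`,
#'   `angle` (degrees, unwrapped, cue frame) and attribute `frame`.
#' @export
lab_to_frame <- function(traj, profile, frame_origin = NULL) {
  stopifnot(inherits(traj, "angular_trajectory"), inherits(profile, "gain_profile"))
  th <- traj$lab_angle
  if (is.null(frame_origin)) frame_origin <- th[1]
  I <- gain_integral(profile, th)
  out <- data.frame(time = traj$time, angle = frame_origin + I - I[1])
  attr(out, "frame") <- profile$cue
  class(out) <- c("frame_position", "data.frame")
  out
}

#' Rotation of the visual cue relative to the laboratory
#'
#' The cue rotation angle phi(t) = theta_lab(t) - theta_frame(t). Its rate
#' is the animal's angular speed times (1 - G): for G > 1 the cue rotates
#' opposite to the running direction, for G = 0 it co-rotates with the
#' animal, and for G = 1 it is identically zero (stationary landmarks).
#'
#' @inheritParams lab_to_frame
#' @return Data frame with columns `time`, `rotation` (degrees).
#' @export
cue_rotation <- function(traj, profile) {
  fp <- lab_to_frame(traj, profile)
  data.frame(time = traj$time, rotation = traj$lab_angle - fp$angle)
}

#' Angular error of the visual scene induced by feedback latency
#'
#' The cue moves at the animal's angular speed times `|1 - G|`; a feedback
#' latency displaces the rendered cue by that rate times the latency.
#'
#' @param rat_angular_speed Animal angular running speed, deg/s.
#' @param gain Dimensionless experiment gain.
#' @param latency Feedback latency in seconds (non-negative).
#' @return Angular error in degrees.
#' @export
#' @examples
#' latency_angular_error(20, 2, 0.1) # 2 degrees
latency_angular_error <- function(rat_angular_speed, gain, latency) {
  if (any(latency < 0)) stop("latency must be non-negative")
  rat_angular_speed * abs(1 - gain) * latency
}

#' Arc length subtended by an angular error
#'
#' @param angular_error Angular error in degrees.
#' @param radius Radius in meters (e.g. the dome equator radius).
#' @return Arc length in meters.
#' @export
#' @examples
#' arc_error(2, 1.15) # ~0.04 m at the equator of a 2.3 m dome
arc_error <- function(angular_error, radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  radius * angular_error * pi / 180
}
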