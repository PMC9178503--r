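# Angular bookkeeping on the circular track. All public angles are in
# degrees; the unwrapped (cumulative, laps x 360 + wrapped) representation
# is canonical and the wrapped view is derived from it.

#' Wrap angles into [0, 360)
#'
#' @param angle_deg Numeric vector of angles in degrees (any range).
#' @return Angles wrapped into `[0, 360)`.
#' @export
#' @examples
#' wrap_angle(c(725, -10))
wrap_angle <- function(angle_deg) {
  angle_deg %% 360
}

#' Unwrap a sequence of wrapped angles
#'
#' Reconstructs a cumulative angle series from wrapped samples, assuming
#' consecutive samples differ by less than 180 degrees. Steps of 180 degrees
#' or more are ambiguous on the circle and trigger a warning.
#'
#' @param angle_deg Numeric vector of wrapped angles in degrees.
#' @return Unwrapped (cumulative) angle series starting at `angle_deg[1]`.
#' @export
unwrap_angle <- function(angle_deg) {
  if (length(angle_deg) < 2L) return(angle_deg)
  step <- diff(angle_deg) %% 360
  step[step >= 180] <- step[step >= 180] - 360
  if (any(abs(step) >= 180 - 1e-9)) {
    warning("steps of 180 degrees or more between samples; unwrapping is ambiguous")
  }
  angle_deg[1] + c(0, cumsum(step))
}

#' Lap index of unwrapped angles
#'
#' Laps are indexed from 0: an unwrapped angle in `[0, 360)` lies on lap 0.
#'
#' @param angle_deg Unwrapped angles in degrees.
#' @return Integer lap indices, `floor(angle / 360)`.
#' @export
lap_count <- function(angle_deg) {
  as.integer(floor(angle_deg / 360))
}

#' Signed angular difference
#'
#' Signed difference `a - b` on the circle, mapped into `(-180, 180]`.
#'
#' @param a,b Angles in degrees.
#' @return Signed wrapped differences in degrees.
#' @export
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# wrap into (-180, 180]
wrap180 <- function(x) ang_diff(x, 0)

#' Circular mean of angles
#'
#' @param angle_deg Angles in degrees.
#' @return Circular mean in `[0, 360)`.
#' @export
circ_mean <- function(angle_deg) {
  r <- pi / 180
  wrap_angle(atan2(mean(sin(angle_deg * r)), mean(cos(angle_deg * r))) / r)
}

# circular distance (unsigned), degrees
circ_dist <- function(a, b) abs(ang_diff(a, b))

#' Convert linear running speed to angular speed
#'
#' @param speed_cm_s Linear speed in cm/s.
#' @param track_radius Track radius in cm.
#' @return Angular speed in deg/s.
#' @export
#' @examples
#' angular_speed(25, 75) # ~20 deg/s on a 150 cm-diameter table
angular_speed <- function(speed_cm_s, track_radius) {
  speed_cm_s / track_radius * 180 / pi
}
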