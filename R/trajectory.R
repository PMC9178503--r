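# Timestamped angular trajectory of the animal in the laboratory frame.

#' Angular trajectory of the animal
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param lab_angle Unwrapped lab-frame angle in degrees.
#' @param speed Linear speed in cm/s (non-negative). If `NULL`, derived
#'   from the angle by central differences smoothed over a 0.25 s window.
#' @param track_radius Track radius in cm.
#' @return Data frame of class `angular_trajectory` with columns `time`,
#'   `lab_angle`, `speed`, and attribute `track_radius`.
#' @export
angular_trajectory <- function(time, lab_angle, speed = NULL, track_radius = 75) {
  stopifnot(length(time) == length(lab_angle), track_radius > 0)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (is.null(speed)) {
    speed <- derive_speed(time, lab_angle, track_radius)
  }
  stopifnot(length(speed) == length(time))
  if (any(speed < 0)) stop("speed must be non-negative")
  out <- data.frame(time = time, lab_angle = lab_angle, speed = speed)
  attr(out, "track_radius") <- track_radius
  class(out) <- c("angular_trajectory", "data.frame")
  out
}

# Linear speed from the angle series: central differences, then a running
# mean over ~0.25 s (the sampling estimator is otherwise very noisy).
derive_speed <- function(time, lab_angle, track_radius, window_s = 0.25) {
  n <- length(time)
  if (n < 2L) return(rep(0, n))
  lo <- c(1, 1:(n - 1)) # central differences; one-sided at the ends
  hi <- c(2:n, n)
  w <- (lab_angle[hi] - lab_angle[lo]) / (time[hi] - time[lo]) # deg/s
  dt <- stats::median(diff(time))
  k <- max(1L, round(window_s / dt))
  if (k > 1L) {
    kern <- rep(1 / k, k)
    w <- stats::filter(w, kern, sides = 2)
    w <- as.numeric(w)
    na <- is.na(w)
    if (any(na)) { # extend the first/last smoothed value to the ends
      idx <- which(!na)
      w[na] <- w[idx[findInterval(which(na), idx, all.inside = TRUE)]]
    }
  }
  abs(w) * pi / 180 * track_radius
}

#' @export
print.angular_trajectory <- function(x, ...) {
  cat("Angular trajectory:", nrow(x), "samples over",
      round(max(x$time) - min(x$time), 1), "s;",
      round((max(x$lab_angle) - min(x$lab_angle)) / 360, 1), "lab laps\n")
  invisible(x)
}

# number of complete laps traversed in a frame
frame_laps_run <- function(traj, profile = NULL) {
  ang <- if (is.null(profile)) traj$lab_angle else lab_to_frame(traj, profile)$angle
  floor((max(ang) - min(ang)) / 360)
}

# time range of a set of epochs (1..4) given trajectory + profile
epoch_time_range <- function(traj, profile, epochs) {
  ep <- epoch_of(profile, traj$lab_angle - traj$lab_angle[1])
  sel <- ep %in% epochs
  if (!any(sel)) stop("no trajectory samples in requested epochs")
  range(traj$time[sel])
}

# subset a trajectory (and optionally spikes) to a time window
clip_trajectory <- function(traj, t_range) {
  keep <- traj$time >= t_range[1] & traj$time <= t_range[2]
  out <- traj[keep, , drop = FALSE]
  attr(out, "track_radius") <- attr(traj, "track_radius")
  class(out) <- class(traj)
  out
}
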