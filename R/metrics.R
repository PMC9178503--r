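# Rate maps, spatial information, reliability, scaling, drift, and
# interspike-interval histograms, computable in any reference frame.

#' Occupancy-corrected firing rate map
#'
#' Bins the track (default 72 bins of 5 degrees) in the requested frame
#' and computes per-bin firing rates from all data where the animal's
#' speed exceeds the threshold (default 5 cm/s). The mean rate is the
#' occupancy-weighted grand mean: total included spikes over total
#' included time.
#'
#' @param spike_times Spike times, s.
#' @param traj An [angular_trajectory()].
#' @param profile A [gain_profile()] (required for cue frames).
#' @param frame `"lab"`, `"landmark"`, or `"stripe"`.
#' @param n_bins Number of angular bins tiling 360 degrees.
#' @param speed_threshold Speed gate, cm/s; samples and spikes at or below
#'   it are excluded.
#' @param time_range Optional length-2 window restricting the data, s.
#' @return List of class `rate_map`: `frame`, `n_bins`, `bin_width`,
#'   `breaks`, `occupancy` (s per bin), `counts`, `rate` (spikes/s; `NA`
#'   for unoccupied bins), `mean_rate`.
#' @export
rate_map <- function(spike_times, traj, profile = NULL,
                     frame = c("lab", "landmark", "stripe"), n_bins = 72,
                     speed_threshold = 5, time_range = NULL) {
  frame <- match.arg(frame)
  stopifnot(inherits(traj, "angular_trajectory"))
  if (!is.null(time_range)) {
    traj <- clip_trajectory(traj, time_range)
    spike_times <- spike_times[spike_times >= time_range[1] &
                                 spike_times <= time_range[2]]
  }
  ang <- if (frame == "lab") traj$lab_angle else {
    stopifnot(inherits(profile, "gain_profile"))
    if (profile$cue != frame) stop("profile cue does not match requested frame")
    lab_to_frame(traj, profile)$angle
  }
  incl <- traj$speed > speed_threshold
  if (!any(incl)) stop("no samples above the speed threshold; empty rate map")
  dt <- c(diff(traj$time), 0)
  dt[length(dt)] <- dt[length(dt) - 1]
  bin_width <- 360 / n_bins
  breaks <- seq(0, 360, by = bin_width)
  bin_of <- function(a) pmin(floor(wrap_angle(a) / bin_width) + 1L, n_bins)
  occupancy <- vapply(seq_len(n_bins), function(b) {
    sum(dt[incl & bin_of(ang) == b])
  }, numeric(1))
  sp_ang <- stats::approx(traj$time, ang, spike_times, rule = 2)$y
  sp_speed <- stats::approx(traj$time, traj$speed, spike_times, rule = 2)$y
  sp_keep <- sp_speed > speed_threshold
  counts <- tabulate(bin_of(sp_ang[sp_keep]), nbins = n_bins)
  rate <- ifelse(occupancy > 0, counts / occupancy, NA_real_)
  structure(list(frame = frame, n_bins = n_bins, bin_width = bin_width,
                 breaks = breaks, occupancy = occupancy, counts = counts,
                 rate = rate, mean_rate = sum(counts) / sum(occupancy)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat("Rate map (", x$frame, " frame): ", x$n_bins, " bins x ",
      x$bin_width, " deg; mean rate ", signif(x$mean_rate, 3),
      " Hz, peak ", signif(max(x$rate, na.rm = TRUE), 3), " Hz\n", sep = "")
  invisible(x)
}

#' Spatial information score
#'
#' The default (`definition = "rate"`) is the per-bin averaged score
#' `(1/B) * sum_i lambda_i * log2(lambda_i / lambda)`, where `B` is the
#' total number of bins, `lambda_i` the occupancy-corrected rate in bin i,
#' and `lambda` the unit's mean rate; zero-rate and unoccupied bins
#' contribute 0 (the `x log x -> 0` limit). The conventional
#' occupancy-weighted bits-per-spike score is available as
#' `definition = "bits_per_spike"`.
#'
#' @param map A [rate_map()].
#' @param definition `"rate"` (per-bin averaged, in Hz-weighted bits) or
#'   `"bits_per_spike"`.
#' @return The information score (0 for a uniform map).
#' @export
spatial_information <- function(map, definition = c("rate", "bits_per_spike")) {
  definition <- match.arg(definition)
  stopifnot(inherits(map, "rate_map"))
  lam <- map$mean_rate
  if (!is.finite(lam) || lam <= 0) stop("mean rate is zero; information undefined")
  li <- map$rate
  ok <- !is.na(li) & li > 0
  if (definition == "rate") {
    sum(li[ok] * log2(li[ok] / lam)) / map$n_bins
  } else {
    p <- map$occupancy / sum(map$occupancy)
    sum(p[ok] * (li[ok] / lam) * log2(li[ok] / lam))
  }
}

#' Peak firing rate of a rate map
#'
#' @param map A [rate_map()].
#' @return Maximum rate over occupied bins, spikes/s.
#' @export
peak_rate <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  if (all(is.na(map$rate))) stop("no occupied bins")
  max(map$rate, na.rm = TRUE)
}

#' Reliability of a place field
#'
#' Fraction of frame laps on which the field produced at least one sweep:
#' `r_p` = (# distinct laps with a sweep) / (# laps run in the frame).
#'
#' @param field A `place_field`.
#' @param laps_run Number of laps the animal ran in the field's frame
#'   (see [lab_to_frame()] and `floor(span / 360)`).
#' @return `r_p` in `[0, 1]`.
#' @export
reliability <- function(field, laps_run) {
  stopifnot(inherits(field, "place_field"), laps_run >= 1)
  length(unique(field$sweeps$lap)) / laps_run
}

#' Per-sweep place-field scaling factors
#'
#' `f_p` = (mean lab-frame sweep size during Epoch 1) / (lab-frame size of
#' the sweep). If field size in the lab frame scales with the experiment
#' gain, `f_p` equals the sweep gain `g_p`.
#'
#' @param field A `place_field` whose sweeps carry `lab_extent` and
#'   `epoch` (see [annotate_sweeps()]).
#' @return Numeric vector of `f_p`, one per sweep (in sweep order).
#' @export
scaling_factor <- function(field) {
  stopifnot(inherits(field, "place_field"))
  sw <- field$sweeps
  if (is.null(sw$lab_extent) || is.null(sw$epoch)) {
    stop("sweeps lack lab_extent/epoch; run annotate_sweeps() first")
  }
  e1 <- sw$epoch == 1L
  if (!any(e1)) stop("field has no Epoch-1 sweeps; scaling undefined")
  mean(sw$lab_extent[e1]) / sw$lab_extent
}

#' Drift rate of a place field
#'
#' Signed angular displacement of the field in its frame per lab lap:
#' `d_p = ang(m_end, m_start) / lab_laps_run`, where `m_start`/`m_end`
#' are circular means of the first/last three sweep centers and `ang` is
#' the signed wrapped difference in `(-180, 180]` (positive in the
#' running direction).
#'
#' @param field A `place_field`.
#' @param lab_laps_run Number of laps the animal ran in the lab frame.
#' @return `d_p` in degrees per lab lap. Fields with fewer than three
#'   sweeps per end use all sweeps, with a warning; fewer than two sweeps
#'   is an error.
#' @export
drift_rate <- function(field, lab_laps_run) {
  stopifnot(inherits(field, "place_field"), lab_laps_run >= 1)
  sw <- field$sweeps[order(field$sweeps$lap), , drop = FALSE]
  n <- nrow(sw)
  if (n < 2L) stop("drift undefined for fields with fewer than two sweeps")
  k <- min(3L, n)
  if (n < 6L) warning("fewer than three sweeps per end; drift uses overlapping sets")
  m_start <- circ_mean(wrap_angle(sw$center[1:k]))
  m_end <- circ_mean(wrap_angle(sw$center[(n - k + 1):n]))
  ang_diff(m_end, m_start) / lab_laps_run
}

#' Circular-mean center of a place field
#'
#' @param field A `place_field`.
#' @return Wrapped field center in degrees.
#' @export
field_center <- function(field) {
  circ_mean(wrap_angle(field$sweeps$center))
}

#' Interspike-interval histogram
#'
#' Histogram of consecutive interspike intervals, excluding intervals
#' greater than `max_isi` (default 0.5 s).
#'
#' @param spike_times Sorted spike times, s.
#' @param max_isi Largest interval retained, s.
#' @param bin_width Histogram bin width, s.
#' @return List: `breaks`, `mids` (s), `counts`.
#' @export
isi_histogram <- function(spike_times, max_isi = 0.5, bin_width = 0.01) {
  stopifnot(!is.unsorted(spike_times))
  isi <- diff(spike_times)
  isi <- isi[isi <= max_isi]
  breaks <- seq(0, max_isi + bin_width * 1e-9, by = bin_width)
  if (breaks[length(breaks)] < max_isi) breaks <- c(breaks, max_isi)
  counts <- if (length(isi)) {
    h <- graphics::hist(isi, breaks = breaks, plot = FALSE)
    h$counts
  } else rep(0L, length(breaks) - 1L)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts)
}
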