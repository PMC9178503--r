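# Place-field sweep detection and clustering.
#
# Spike locations in the unwrapped landmark frame are convolved with a
# Gaussian kernel density (0.5 degree grid, bandwidth 8 degrees); each
# traversal of a field appears as a separate peak in unwrapped
# coordinates. A sweep is the contiguous region around a peak where the
# density exceeds 10% of that peak, gated to 5-120 degrees. Sweeps with
# too few spikes or too few neighbors (within 15 degrees wrapped and a
# 15-lap window) are deleted iteratively; surviving sweeps are clustered
# into place fields by connected proximity.

#' Detection parameters
#'
#' @param kde_bin KDE grid spacing, degrees.
#' @param kde_bandwidth Gaussian kernel s.d., degrees.
#' @param peak_fraction Fraction of a peak's density defining its sweep
#'   boundaries.
#' @param min_sweep,max_sweep Sweep size gates, degrees.
#' @param window_laps Width of the lap window used for proximity (the
#'   window is centered on a sweep's lap, excluding that lap itself).
#' @param proximity Maximum wrapped angular distance between sweep centers
#'   for proximity, degrees.
#' @param min_proximal Minimum number of proximal sweeps a sweep needs to
#'   survive deletion.
#' @param min_spikes Minimum spikes per sweep.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(kde_bin = 0.5, kde_bandwidth = 8,
                             peak_fraction = 0.10, min_sweep = 5,
                             max_sweep = 120, window_laps = 15,
                             proximity = 15, min_proximal = 3,
                             min_spikes = 4) {
  stopifnot(kde_bin > 0, kde_bandwidth > 0,
            peak_fraction > 0, peak_fraction < 1,
            min_sweep > 0, min_sweep < max_sweep,
            window_laps >= 1, proximity > 0, min_proximal >= 0, min_spikes >= 0)
  structure(as.list(environment()), class = "detection_params")
}

#' Firing-rate analogue by kernel density estimation
#'
#' Gaussian-kernel density of spike locations in the unwrapped cue frame,
#' evaluated on a regular grid spanning the spike range padded by three
#' bandwidths. The density integrates to ~1 over the grid.
#'
#' @param spike_angles Spike locations, degrees, unwrapped.
#' @param params A [detection_params()].
#' @return List of class `rate_analogue`: `grid` (degrees), `density`.
#'   Empty input yields empty vectors.
#' @export
firing_rate_analogue <- function(spike_angles, params = detection_params()) {
  if (length(spike_angles) == 0L) {
    return(structure(list(grid = numeric(0), density = numeric(0)),
                     class = "rate_analogue"))
  }
  bw <- params$kde_bandwidth; bin <- params$kde_bin
  lo <- floor((min(spike_angles) - 3 * bw) / bin) * bin
  hi <- ceiling((max(spike_angles) + 3 * bw) / bin) * bin
  n <- round((hi - lo) / bin) + 1L
  grid <- lo + (seq_len(n) - 1L) * bin
  # exact grid evaluation: bin the spikes, FFT-convolve with the Gaussian
  # kernel (truncated at 6 bandwidths, amplitude < 1e-8 of peak there);
  # spline-interpolated FFT densities leave flank ripples that masquerade
  # as peaks, so the convolution is done on the output grid directly
  pos <- (spike_angles - lo) / bin
  i0 <- pmin(pmax(floor(pos) + 1L, 1L), n - 1L) # linear binning: split weight
  w1 <- pos - (i0 - 1L)
  agg <- rowsum(c(1 - w1, w1), group = c(i0, i0 + 1L))
  counts <- numeric(n)
  counts[as.integer(rownames(agg))] <- agg
  L <- ceiling(6 * bw / bin)
  kern <- stats::dnorm(seq(-L, L) * bin, 0, bw)
  dens <- stats::convolve(counts, rev(kern), type = "open")[(L + 1):(L + n)]
  dens <- pmax(dens, 0) / length(spike_angles)
  structure(list(grid = grid, density = dens), class = "rate_analogue")
}

# indices of strict local maxima (plateaus take their left edge)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Detect sweeps from a firing-rate analogue
#'
#' For each local maximum of the density, the sweep is the maximal
#' contiguous grid interval around it where the density exceeds
#' `peak_fraction` times that peak's density. Overlapping intervals from
#' the same threshold region are merged; intervals outside the
#' `[min_sweep, max_sweep]` size gate are discarded.
#'
#' @param fra A `rate_analogue` from [firing_rate_analogue()].
#' @param spike_angles The spike locations the analogue was built from,
#'   degrees, unwrapped.
#' @param params A [detection_params()].
#' @param unit_id Identifier attached to the sweeps.
#' @return Data frame of class `sweep_set`: one row per sweep with
#'   `unit_id`, `start`, `end`, `center` (geometric midpoint), `lap`
#'   (0-based lap of the center), `spike_count`.
#' @export
detect_sweeps <- function(fra, spike_angles, params = detection_params(),
                          unit_id = 1L) {
  empty <- data.frame(unit_id = integer(0), start = numeric(0), end = numeric(0),
                      center = numeric(0), lap = integer(0),
                      spike_count = integer(0))
  class(empty) <- c("sweep_set", "data.frame")
  d <- fra$density
  if (length(d) == 0L) return(empty)
  peaks <- local_maxima(d)
  if (length(peaks) == 0L) return(empty)
  iv <- matrix(NA_integer_, nrow = length(peaks), ncol = 2)
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    thr <- params$peak_fraction * d[p]
    below_left <- which(d[1:p] <= thr)
    lo <- if (length(below_left)) max(below_left) + 1L else 1L
    below_right <- which(d[p:length(d)] <= thr)
    hi <- if (length(below_right)) p + min(below_right) - 2L else length(d)
    # a shoulder peak whose region contains a taller point does not define
    # its own sweep; that region is governed by the taller peak
    if (max(d[lo:hi]) > d[p] * (1 + 1e-12)) next
    iv[k, ] <- c(lo, hi)
  }
  iv <- iv[!is.na(iv[, 1]), , drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  # size-gate per-peak intervals, then merge overlapping threshold
  # regions (two peaks sharing a 10% region) into single sweeps
  width <- (iv[, 2] - iv[, 1]) * params$kde_bin
  iv <- iv[width >= params$min_sweep & width <= params$max_sweep, ,
           drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  o <- order(iv[, 1], iv[, 2])
  iv <- iv[o, , drop = FALSE]
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[k, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[k, 2]))
    } else {
      merged[[length(merged) + 1L]] <- iv[k, ]
    }
  }
  m <- do.call(rbind, merged)
  start <- fra$grid[m[, 1]]
  end <- fra$grid[m[, 2]]
  cnt <- vapply(seq_along(start), function(k) {
    sum(spike_angles >= start[k] & spike_angles <= end[k])
  }, integer(1))
  out <- data.frame(unit_id = rep(unit_id, length(start)),
                    start = start, end = end,
                    center = (start + end) / 2,
                    lap = lap_count((start + end) / 2),
                    spike_count = cnt)
  out <- out[out$spike_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sweep_set", "data.frame")
  out
}

# proximity adjacency between sweeps: centers within `proximity` degrees
# (wrapped) and laps within the window, excluding the same lap
proximity_adjacency <- function(sweeps, params) {
  n <- nrow(sweeps)
  half <- floor(params$window_laps / 2)
  dl <- abs(outer(sweeps$lap, sweeps$lap, "-"))
  da <- abs(outer(sweeps$center, sweeps$center, ang_diff))
  adj <- dl >= 1 & dl <= half & da <= params$proximity
  diag(adj) <- FALSE
  adj
}

#' Filter sweeps and cluster them into place fields
#'
#' Sweeps with fewer than `min_spikes` spikes or fewer than `min_proximal`
#' proximal sweeps are deleted; deletion is iterated to a fixpoint so the
#' result is independent of input order. Surviving sweeps are partitioned
#' into connected components of the proximity graph; each component is a
#' place field (every member is then proximal to at least two others in
#' its field).
#'
#' @param sweeps A `sweep_set` from one unit.
#' @param params A [detection_params()].
#' @return List of `place_field` objects (possibly empty). Each has
#'   `field_id`, `unit_id`, and `sweeps` (a `sweep_set` ordered by lap).
#' @export
filter_and_cluster <- function(sweeps, params = detection_params()) {
  if (nrow(sweeps) == 0L) return(list())
  if (length(unique(sweeps$unit_id)) > 1L) {
    stop("filter_and_cluster expects sweeps from a single unit")
  }
  keep_spk <- sweeps$spike_count >= params$min_spikes
  sw <- sweeps[keep_spk, , drop = FALSE]
  repeat {
    if (nrow(sw) == 0L) return(list())
    adj <- proximity_adjacency(sw, params)
    del <- rowSums(adj) < params$min_proximal
    if (!any(del)) break
    sw <- sw[!del, , drop = FALSE]
  }
  comp <- graph_components(adj)
  fields <- lapply(seq_len(max(comp)), function(k) {
    s <- sw[comp == k, , drop = FALSE]
    s <- s[order(s$lap, s$center), , drop = FALSE]
    rownames(s) <- NULL
    class(s) <- c("sweep_set", "data.frame")
    structure(list(field_id = k, unit_id = s$unit_id[1], sweeps = s),
              class = "place_field")
  })
  fields
}

# connected components of an undirected adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.place_field <- function(x, ...) {
  cat("Place field", x$field_id, "(unit", x$unit_id, "):",
      nrow(x$sweeps), "sweeps, laps", min(x$sweeps$lap), "-",
      max(x$sweeps$lap), ", center ~",
      round(circ_mean(wrap_angle(x$sweeps$center)), 1), "deg\n")
  invisible(x)
}

#' Merge place fields (manual curation)
#'
#' Union of the sweeps of the given fields as a single field. Curation
#' overrides the proximity invariant, mirroring manual merge of fields an
#' automated pass over-segmented.
#'
#' @param fields List of `place_field` objects.
#' @param ids_to_merge Vector of `field_id`s to merge (must share a unit).
#' @return New list of fields with the merged field replacing its parts.
#' @export
merge_fields <- function(fields, ids_to_merge) {
  ids <- vapply(fields, `[[`, numeric(1), "field_id")
  sel <- ids %in% ids_to_merge
  if (!any(sel)) stop("no fields with the given ids")
  parts <- fields[sel]
  units <- unique(vapply(parts, `[[`, numeric(1), "unit_id"))
  if (length(units) > 1L) stop("cannot merge fields from different units")
  sw <- unique(do.call(rbind, lapply(parts, `[[`, "sweeps")))
  sw <- sw[order(sw$lap, sw$center), , drop = FALSE]
  rownames(sw) <- NULL
  class(sw) <- c("sweep_set", "data.frame")
  merged <- structure(list(field_id = min(ids[sel]), unit_id = units,
                           sweeps = sw), class = "place_field")
  c(fields[!sel], list(merged))
}

#' Annotate sweeps with laboratory-frame extent and sweep gain
#'
#' Maps each sweep's start/end back through the trajectory to lab-frame
#' angles, giving the lab-frame extent traversed during the sweep, the
#' sweep gain `g_p` (mean of the experiment gain at start and end), and
#' the epoch of the sweep center.
#'
#' @param sweeps A `sweep_set` (in the profile's cue frame).
#' @param traj An [angular_trajectory()].
#' @param profile A [gain_profile()].
#' @return The sweeps with columns `lab_start`, `lab_end`, `lab_extent`,
#'   `g_p`, `epoch` added.
#' @export
annotate_sweeps <- function(sweeps, traj, profile) {
  if (nrow(sweeps) == 0L) {
    sweeps$lab_start <- sweeps$lab_end <- sweeps$lab_extent <-
      sweeps$g_p <- numeric(0)
    sweeps$epoch <- integer(0)
    return(sweeps)
  }
  fr <- lab_to_frame(traj, profile)$angle
  lab0 <- traj$lab_angle[1]
  to_lab <- function(a) stats::approx(fr, traj$lab_angle, a, ties = "ordered",
                                      rule = 2)$y
  ls <- to_lab(sweeps$start)
  le <- to_lab(sweeps$end)
  sweeps$lab_start <- ls
  sweeps$lab_end <- le
  sweeps$lab_extent <- le - ls
  sweeps$g_p <- (gain_at(profile, ls - lab0) + gain_at(profile, le - lab0)) / 2
  sweeps$epoch <- epoch_of(profile, (ls + le) / 2 - lab0)
  sweeps
}

#' Sweep gain
#'
#' The gain `g_p` of a sweep: the mean of the experiment gain at the
#' sweep's start and end positions.
#'
#' @param sweep One-row `sweep_set` (or any row with `start`/`end`).
#' @param traj,profile Trajectory and gain profile of the session.
#' @return Dimensionless `g_p`.
#' @export
assign_sweep_gain <- function(sweep, traj, profile) {
  annotate_sweeps(sweep, traj, profile)$g_p
}

#' Gain bin of a place field
#'
#' Bins a field by the sweep gain of its last sweep (the last gain at
#' which the cell was active). Default edges give five ranges with a
#' lowest bin of 0-0.6.
#'
#' @param field A `place_field` whose sweeps carry `g_p` (see
#'   [annotate_sweeps()]).
#' @param bin_edges Increasing numeric vector of bin edges.
#' @return The bin label as a factor level `"(lo,hi]"` (lowest bin closed
#'   at 0). Gains outside the edges fall in an overflow bin with a
#'   warning.
#' @export
field_gain_bin <- function(field, bin_edges = c(0, 0.6, 0.9, 1.1, 1.4, 2)) {
  stopifnot(inherits(field, "place_field"), nrow(field$sweeps) > 0)
  if (is.null(field$sweeps$g_p)) stop("sweeps lack g_p; run annotate_sweeps() first")
  last <- field$sweeps[which.max(field$sweeps$lap), , drop = FALSE]
  g <- last$g_p[nrow(last)]
  labs <- paste0("(", utils::head(bin_edges, -1), ",", bin_edges[-1], "]")
  k <- findInterval(g, bin_edges, left.open = TRUE, rightmost.closed = FALSE)
  if (g == bin_edges[1]) k <- 1L
  if (k < 1L || k > length(labs)) {
    warning("last-sweep gain ", signif(g, 4), " outside bin edges; overflow bin")
    return("overflow")
  }
  labs[k]
}
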