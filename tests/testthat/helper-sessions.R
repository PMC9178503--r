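# Shared fixtures: small synthetic sessions built in code at test time.

# canonical ramp profile: 15 + 10 + 15 laps, no dark epoch
ramp_profile <- function(final_gain = 1.5, epoch_laps = c(15, 10, 15, 0)) {
  gain_profile(epoch_laps = epoch_laps, final_gain = final_gain)
}

# short session with landmark-locked cells; noiseless by default so
# detection/metric recovery is limited by the method, not Poisson noise
small_session <- function(final_gain = 1.5, centers = c(90, 250),
                          session_laps = 25, seed = 42, noiseless = TRUE,
                          width = 40, peak_rate = 15, baseline_rate = 0,
                          lfp_args = NULL, behavior_args = list(),
                          epoch_laps = c(15, 10, 15, 0), ...) {
  cells <- lapply(centers, function(ctr) {
    place_cell_spec(center = ctr, width = width, peak_rate = peak_rate,
                    baseline_rate = baseline_rate, ...)
  })
  beh <- do.call(behavior_config,
                 c(list(session_laps = session_laps, seed = seed), behavior_args))
  simulate_session(beh, ramp_profile(final_gain, epoch_laps), cells,
                   lfp_args = lfp_args, noiseless = noiseless)
}

# spike angles in the profile's cue frame
frame_spike_angles <- function(session, unit = 1) {
  fr <- lab_to_frame(session$trajectory, session$profile)
  stats::approx(session$trajectory$time, fr$angle, session$spikes[[unit]])$y
}

# detect + annotate + cluster one unit of a session
detect_fields <- function(session, unit = 1, params = detection_params()) {
  spa <- frame_spike_angles(session, unit)
  sw <- detect_sweeps(firing_rate_analogue(spa, params), spa, params,
                      unit_id = unit)
  sw <- annotate_sweeps(sw, session$trajectory, session$profile)
  filter_and_cluster(sw, params)
}

# brute-force optimal monotone matching score between two interval
# sequences under the same scoring as align_pulse_trains (oracle)
nw_oracle_score <- function(da, db, gap_penalty = -1, interval_tolerance = 0.1) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i > length(da)) return(gap_penalty * (length(db) - j + 1))
    if (j > length(db)) return(gap_penalty * (length(da) - i + 1))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- max(rec(i + 1, j + 1) - abs(da[i] - db[j]) / interval_tolerance,
                rec(i + 1, j) + gap_penalty,
                rec(i, j + 1) + gap_penalty)
    memo[[key]] <- best
    best
  }
  rec(1, 1)
}

# independent clustering oracle: fixpoint deletion re-derived with a
# while-loop over row indices in a caller-chosen order, then connected
# components via boolean matrix reachability (no BFS shared with the
# implementation); returns sorted sweep-center sets
cluster_oracle <- function(sweeps, params = detection_params(),
                           order_idx = seq_len(nrow(sweeps))) {
  sweeps <- sweeps[order_idx, , drop = FALSE]
  sweeps <- sweeps[sweeps$spike_count >= params$min_spikes, , drop = FALSE]
  repeat {
    if (nrow(sweeps) == 0) return(list())
    adj <- gaintrack:::proximity_adjacency(sweeps, params)
    del <- rowSums(adj) < params$min_proximal
    if (!any(del)) break
    sweeps <- sweeps[!del, , drop = FALSE]
  }
  n <- nrow(sweeps)
  reach <- diag(TRUE, n) | adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp_of <- apply(reach, 1, function(r) min(which(r)))
  sets <- lapply(unique(comp_of), function(c0) {
    idx <- which(comp_of == c0)
    stopifnot(all(rowSums(adj[idx, idx, drop = FALSE]) >= 2)) # field invariant
    sort(sweeps$center[idx])
  })
  sets[order(vapply(sets, min, numeric(1)))]
}
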