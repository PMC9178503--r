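# Synthetic session generator. Produces trajectories with run/pause
# structure calibrated to the published behavioral summaries (running
# speed ~24.6 cm/s, ~0.9 pauses per lap, ~8.8 s pauses), frame-locked
# place-cell spike trains by inhomogeneous-Poisson thinning, a theta-band
# LFP with stored ground-truth phase, and randomized TTL sync pulse
# trains. Every generator is deterministic under its seed.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Behavioral configuration for the trajectory simulator
#'
#' Defaults emulate the published Epoch-1 behavioral summaries: running
#' speed 24.6 cm/s, 0.9 pauses per lap, 8.8 s mean pause duration, on a
#' 150 cm-diameter table.
#'
#' @param mean_speed Mean running speed, cm/s.
#' @param speed_sd Between-bout s.d. of running speed, cm/s.
#' @param pauses_per_lap Expected number of pauses per lab lap (pause
#'   onsets form a Poisson process in distance).
#' @param pause_duration_mean Mean pause duration, s (gamma distributed).
#' @param pause_duration_shape Gamma shape of pause durations.
#' @param track_radius Track radius, cm.
#' @param session_laps Lab-frame laps to simulate.
#' @param sample_rate Trajectory sampling rate, Hz (camera-rate analogue).
#' @param seed Integer RNG seed.
#' @return List of class `behavior_config`.
#' @export
behavior_config <- function(mean_speed = 24.6, speed_sd = 2.5,
                            pauses_per_lap = 0.9, pause_duration_mean = 8.8,
                            pause_duration_shape = 2, track_radius = 75,
                            session_laps = 40, sample_rate = 50, seed = 1L) {
  stopifnot(mean_speed > 0, speed_sd >= 0, pauses_per_lap >= 0,
            pause_duration_mean > 0, pause_duration_shape > 0,
            track_radius > 0, session_laps > 0, sample_rate >= 45)
  structure(as.list(environment()), class = "behavior_config")
}

#' Simulate a run/pause trajectory on the circular track
#'
#' Alternating run bouts and pauses: bout speeds are drawn from a normal
#' distribution truncated below at 5 cm/s; pause onsets are a Poisson
#' process in lab distance; pause durations are gamma distributed.
#'
#' @param config A [behavior_config()].
#' @return An [angular_trajectory()] covering `session_laps` lab laps.
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "behavior_config"))
  with_seed(config$seed, {
    dt <- 1 / config$sample_rate
    end_angle <- config$session_laps * 360
    draw_speed <- function() {
      repeat {
        s <- stats::rnorm(1, config$mean_speed, config$speed_sd)
        if (s > 5) return(s)
      }
    }
    draw_gap <- function() { # lab degrees until next pause onset
      if (config$pauses_per_lap <= 0) Inf
      else stats::rexp(1, rate = config$pauses_per_lap) * 360
    }
    n_guess <- ceiling((end_angle / angular_speed(config$mean_speed, config$track_radius) +
                          config$session_laps * config$pauses_per_lap *
                          config$pause_duration_mean * 1.5 + 60) / dt)
    time <- numeric(n_guess); ang <- numeric(n_guess); spd <- numeric(n_guess)
    i <- 1L; t <- 0; a <- 0
    bout_speed <- draw_speed()
    next_pause <- draw_gap()
    pause_left <- 0
    while (a < end_angle) {
      running <- pause_left <= 0
      v <- if (running) bout_speed else 0
      time[i] <- t; ang[i] <- a; spd[i] <- v
      if (running) {
        a <- a + angular_speed(v, config$track_radius) * dt
        if (a >= next_pause) {
          pause_left <- stats::rgamma(1, shape = config$pause_duration_shape,
                                      scale = config$pause_duration_mean /
                                        config$pause_duration_shape)
          next_pause <- a + draw_gap()
        }
      } else {
        pause_left <- pause_left - dt
        if (pause_left <= 0) bout_speed <- draw_speed()
      }
      t <- t + dt
      i <- i + 1L
      if (i > length(time)) { # extend storage if pauses ran long
        time <- c(time, numeric(n_guess)); ang <- c(ang, numeric(n_guess))
        spd <- c(spd, numeric(n_guess))
      }
    }
    # final sample at (or just past) the session-end crossing
    time[i] <- t; ang[i] <- a; spd[i] <- bout_speed
    angular_trajectory(time[1:i], ang[1:i], spd[1:i], config$track_radius)
  })
}

#' Simulate a theta-band LFP with known phase
#'
#' A sinusoid at the theta frequency (default 8 Hz, inside the 6-12 Hz
#' band) plus white noise. The ground-truth instantaneous phase is stored
#' so extraction accuracy can be scored.
#'
#' @param theta_freq Frequency in Hz: a scalar, or a vector of length equal
#'   to the number of samples for a time-varying (e.g. swept) frequency.
#' @param amplitude Sinusoid amplitude.
#' @param noise_sd S.d. of additive white noise.
#' @param duration Duration, s.
#' @param rate Sampling rate, Hz (must be at least 4 x theta_freq).
#' @param seed Integer RNG seed.
#' @return List of class `lfp`: `time`, `value`, `rate`,
#'   `truth_phase` (unwrapped degrees; 0 at signal peaks).
#' @export
simulate_lfp <- function(theta_freq = 8, amplitude = 1, noise_sd = 0,
                         duration = 60, rate = 250, seed = 1L) {
  n <- floor(duration * rate) + 1L
  time <- (seq_len(n) - 1) / rate
  f <- if (length(theta_freq) == 1L) rep(theta_freq, n) else theta_freq
  stopifnot(length(f) == n, rate >= 4 * max(f))
  phase <- cumsum(c(0, 360 * (f[-1] + f[-n]) / 2 / rate)) # trapezoid in deg
  value <- amplitude * cos(phase * pi / 180)
  if (noise_sd > 0) value <- value + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  structure(list(time = time, value = value, rate = rate, truth_phase = phase),
            class = "lfp")
}

#' Specification of a simulated place cell
#'
#' Ground truth for one unit: a circular-Gaussian tuning curve in its
#' owning frame, optional theta modulation with linear phase precession
#' across the field, optional remapping (active lap range) and drift.
#'
#' @param frame Frame the tuning is locked to: `"lab"`, `"landmark"`, or
#'   `"stripe"`.
#' @param center Field center, degrees, in the owning frame.
#' @param width Full tuning width at 10% of peak, degrees (matches the
#'   sweep detector's size definition).
#' @param peak_rate,baseline_rate Firing rates, spikes/s.
#' @param active_lap_range Length-2 integer vector `[first, last]` of laps
#'   (0-based, in the owning frame) on which the field is expressed;
#'   `NULL` means the whole session.
#' @param drift_per_lab_lap Field-center drift, degrees per lab lap.
#' @param theta_modulation_depth Theta modulation depth in `[0, 1]`.
#' @param precession_span Degrees of theta phase traversed across the
#'   field (phase decreases with progress through the field).
#' @param immobile_rate_fraction Fraction of the place-specific rate
#'   retained while the animal is immobile (speed at or below 5 cm/s).
#'   Hippocampal place-field firing is strongly attenuated during
#'   immobility, so the default is 0 (baseline only while paused).
#' @return List of class `place_cell_spec`.
#' @export
place_cell_spec <- function(frame = c("landmark", "lab", "stripe"), center = 180,
                            width = 40, peak_rate = 15, baseline_rate = 0.1,
                            active_lap_range = NULL, drift_per_lab_lap = 0,
                            theta_modulation_depth = 0, precession_span = 360,
                            immobile_rate_fraction = 0) {
  frame <- match.arg(frame)
  stopifnot(width > 0, peak_rate >= baseline_rate, baseline_rate >= 0,
            theta_modulation_depth >= 0, theta_modulation_depth <= 1,
            immobile_rate_fraction >= 0, immobile_rate_fraction <= 1)
  if (!is.null(active_lap_range)) stopifnot(length(active_lap_range) == 2)
  structure(as.list(environment()), class = "place_cell_spec")
}

# sigma of the circular Gaussian whose full width at 10% of peak is `width`
tuning_sigma <- function(width) width / (2 * sqrt(2 * log(10)))

#' Simulate a place-cell spike train by Poisson thinning
#'
#' The instantaneous rate is `baseline + (peak - baseline) *
#' tuning(theta_frame(t))` with a circular-Gaussian tuning curve around the
#' (possibly drifting) center, zeroed outside the active lap range, and
#' multiplied by a theta factor `1 + depth * cos(phase - preferred(x))`
#' where the preferred phase falls linearly from `+span/2` to `-span/2`
#' across the field.
#'
#' @param spec A [place_cell_spec()].
#' @param traj An [angular_trajectory()].
#' @param profile A [gain_profile()]; needed when `spec$frame` is a cue
#'   frame, ignored for lab-frame cells.
#' @param lfp An `lfp` object with `truth_phase`; required when
#'   `theta_modulation_depth > 0`.
#' @param seed Integer RNG seed (unused in noiseless mode).
#' @param noiseless If `TRUE`, spikes are generated deterministically by
#'   time rescaling (one spike each time the cumulative intensity crosses
#'   `k - 0.5`), giving a noise-free realization of the same rate
#'   function; useful for recovery tests where Poisson variability would
#'   dominate.
#' @return Sorted numeric vector of spike times, s.
#' @export
simulate_spikes <- function(spec, traj, profile = NULL, lfp = NULL, seed = 1L,
                            noiseless = FALSE) {
  stopifnot(inherits(spec, "place_cell_spec"), inherits(traj, "angular_trajectory"))
  if (spec$frame != "lab") {
    stopifnot(inherits(profile, "gain_profile"))
    if (profile$cue != spec$frame) stop("spec frame does not match profile cue")
    fr_ang <- lab_to_frame(traj, profile)$angle
  } else {
    fr_ang <- traj$lab_angle
  }
  depth <- spec$theta_modulation_depth
  if (depth > 0 && is.null(lfp)) stop("theta modulation requires an lfp with truth phase")
  lam_max <- spec$peak_rate * (1 + depth)
  t0 <- traj$time[1]; t1 <- traj$time[length(traj$time)]
  rate_at <- function(tt) {
    a <- stats::approx(traj$time, fr_ang, tt)$y
    lab <- stats::approx(traj$time, traj$lab_angle, tt)$y
    ctr <- spec$center + spec$drift_per_lab_lap * (lab - traj$lab_angle[1]) / 360
    d <- ang_diff(a, ctr)
    tun <- exp(-0.5 * (d / tuning_sigma(spec$width))^2)
    spd <- stats::approx(traj$time, traj$speed, tt)$y
    tun[spd <= 5] <- tun[spd <= 5] * spec$immobile_rate_fraction
    lam <- spec$baseline_rate + (spec$peak_rate - spec$baseline_rate) * tun
    if (!is.null(spec$active_lap_range)) {
      lap <- lap_count(a - fr_ang[1])
      off <- lap < spec$active_lap_range[1] | lap > spec$active_lap_range[2]
      lam[off] <- spec$baseline_rate
    }
    if (depth > 0) {
      ph <- stats::approx(lfp$time, lfp$truth_phase, tt, rule = 2)$y
      x <- pmin(pmax((d + spec$width / 2) / spec$width, 0), 1)
      pref <- spec$precession_span * (0.5 - x)
      lam <- lam * (1 + depth * cos((wrap180(ph) - pref) * pi / 180))
    }
    lam
  }
  if (noiseless) {
    tt <- seq(t0, t1, by = 1 / 250) # fine grid resolves theta modulation
    lam <- rate_at(tt)
    cum <- cumsum(c(0, (lam[-1] + lam[-length(lam)]) / 2 * diff(tt)))
    total <- cum[length(cum)]
    if (total < 0.5) return(numeric(0))
    ks <- seq(0.5, total, by = 1)
    return(stats::approx(cum, tt, xout = ks, ties = "ordered")$y)
  }
  with_seed(seed, {
    n_cand <- stats::rpois(1, lam_max * (t1 - t0))
    cand <- sort(stats::runif(n_cand, t0, t1))
    lam <- rate_at(cand)
    if (any(lam > lam_max + 1e-9)) stop("thinning envelope exceeded (internal error)")
    cand[stats::runif(n_cand) < lam / lam_max]
  })
}

#' Simulate a randomized TTL sync pulse train
#'
#' Inter-onset intervals are a shifted exponential: a refractory floor of
#' `pulse_width + 0.5` s plus an exponential chosen so the overall mean
#' interval equals `mean_interval`. Pulses never overlap.
#'
#' @param mean_interval Mean interval between pulse onsets, s.
#' @param pulse_width Pulse duration, s.
#' @param duration Train duration, s.
#' @param seed Integer RNG seed.
#' @return A [pulse_train()] with onsets in `[0, duration]`.
#' @export
simulate_pulse_train <- function(mean_interval = 10, pulse_width = 1,
                                 duration = 600, seed = 1L) {
  stopifnot(mean_interval > pulse_width)
  tmin <- pulse_width + 0.5
  stopifnot(mean_interval > tmin)
  with_seed(seed, {
    n_guess <- ceiling(duration / mean_interval * 2) + 10
    iv <- tmin + stats::rexp(n_guess, rate = 1 / (mean_interval - tmin))
    on <- cumsum(iv)
    while (on[length(on)] < duration) {
      iv2 <- tmin + stats::rexp(n_guess, rate = 1 / (mean_interval - tmin))
      on <- c(on, on[length(on)] + cumsum(iv2))
    }
    pulse_train(on[on <= duration], pulse_width)
  })
}

#' Corrupt a pulse train with clock offset, drift, jitter, drops, and
#' spurious pulses
#'
#' Test harness for clock synchronization: maps onsets through
#' `t' = offset + (1 + drift) * t + jitter`, drops each pulse with
#' probability `drop_prob`, and inserts spurious pulses at rate
#' `extra_rate`. The ground-truth correspondence is returned for scoring.
#'
#' @param pulses A [pulse_train()].
#' @param offset Clock offset, s.
#' @param drift Clock drift, s/s.
#' @param jitter_sd S.d. of timestamp jitter, s.
#' @param drop_prob Probability a pulse is lost, in `[0, 1)`.
#' @param extra_rate Rate of spurious insertions, pulses/s.
#' @param seed Integer RNG seed.
#' @return List: `pulses` (corrupted [pulse_train()]), `truth` (data frame
#'   with `orig_index`, `corrupted_index` for surviving pulses).
#' @export
corrupt_clock <- function(pulses, offset = 0, drift = 0, jitter_sd = 0,
                          drop_prob = 0, extra_rate = 0, seed = 1L) {
  stopifnot(inherits(pulses, "pulse_train"), drop_prob >= 0, drop_prob < 1)
  with_seed(seed, {
    t <- pulses$onsets
    n <- length(t)
    tt <- offset + (1 + drift) * t
    if (jitter_sd > 0) tt <- tt + stats::rnorm(n, 0, jitter_sd)
    keep <- stats::runif(n) >= drop_prob
    span <- diff(range(tt))
    extra <- if (extra_rate > 0)
      stats::runif(stats::rpois(1, extra_rate * span), min(tt), max(tt))
    else numeric(0)
    all_t <- c(tt[keep], extra)
    src <- c(which(keep), rep(NA_integer_, length(extra)))
    o <- order(all_t)
    all_t <- all_t[o]; src <- src[o]
    truth <- data.frame(orig_index = src[!is.na(src)],
                        corrupted_index = which(!is.na(src)))
    list(pulses = pulse_train(all_t, pulses$pulse_width, check_gaps = FALSE),
         truth = truth)
  })
}

#' Simulate a complete synthetic session
#'
#' Bundles a trajectory, per-unit spike trains, an LFP, and a sync pulse
#' train, together with the ground truth used to generate them. Unit
#' sub-seeds are derived from the session seed so the session is
#' reproducible and units are independent.
#'
#' @param behavior A [behavior_config()] (its `seed` seeds the session).
#' @param profile A [gain_profile()].
#' @param cells List of [place_cell_spec()] objects.
#' @param lfp_args List of arguments for [simulate_lfp()] (duration and
#'   seed are filled in automatically); `NULL` to skip the LFP.
#' @param pulse_args List of arguments for [simulate_pulse_train()].
#' @param noiseless Passed to [simulate_spikes()]: deterministic
#'   time-rescaled spiking instead of Poisson thinning.
#' @return List of class `synthetic_session`: `trajectory`, `spikes`
#'   (named list of spike-time vectors), `lfp`, `pulses`, `profile`,
#'   `cells`, `seed`.
#' @export
simulate_session <- function(behavior = behavior_config(),
                             profile = gain_profile(),
                             cells = list(),
                             lfp_args = list(theta_freq = 8, amplitude = 1,
                                             noise_sd = 0.2, rate = 250),
                             pulse_args = list(mean_interval = 10, pulse_width = 1),
                             noiseless = FALSE) {
  traj <- simulate_trajectory(behavior)
  duration <- max(traj$time)
  seed <- behavior$seed
  lfp <- if (!is.null(lfp_args)) {
    do.call(simulate_lfp, c(lfp_args, list(duration = duration, seed = seed + 571L)))
  }
  spikes <- list()
  if (length(cells)) {
    spikes <- lapply(seq_along(cells), function(k) {
      simulate_spikes(cells[[k]], traj, profile, lfp, seed = seed + 7919L * k,
                      noiseless = noiseless)
    })
    names(spikes) <- paste0("unit", seq_along(cells))
  }
  pulses <- do.call(simulate_pulse_train,
                    c(pulse_args, list(duration = duration, seed = seed + 131L)))
  structure(list(trajectory = traj, spikes = spikes, lfp = lfp, pulses = pulses,
                 profile = profile, cells = cells, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("Synthetic session:", length(x$spikes), "units,",
      round(max(x$trajectory$time), 1), "s,",
      frame_laps_run(x$trajectory), "lab laps, G_final =",
      x$profile$final_gain, "\n")
  invisible(x)
}
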