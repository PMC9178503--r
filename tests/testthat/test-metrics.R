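test_that("rate maps tile the track in 72 five-degree bins and gate on speed", {
  tm <- seq(0, 600, by = 0.02)
  traj <- angular_trajectory(tm, tm * 19.1, rep(25, length(tm)))
  set.seed(10)
  sp <- sort(runif(3000, 0, 600)) # homogeneous 5 Hz
  m <- rate_map(sp, traj)
  expect_equal(m$n_bins, 72)
  expect_equal(m$bin_width, 5)
  expect_length(m$rate, 72)
  expect_equal(sum(m$occupancy), 600, tolerance = 1)
  # Poisson check: every bin within 3 s.d. of 5 Hz
  expect_true(all(abs(m$counts - 5 * m$occupancy) <=
                    3 * sqrt(pmax(5 * m$occupancy, 1))))
  expect_equal(m$mean_rate, 5, tolerance = 0.2)

  # all samples below the threshold: defined error
  slow <- angular_trajectory(tm, tm * 2, rep(2, length(tm)))
  expect_error(rate_map(sp, slow), "speed threshold")

  # spikes during immobility are excluded
  sp2 <- traj$speed
  traj_mixed <- traj
  traj_mixed$speed[tm < 300] <- 0
  attr(traj_mixed, "track_radius") <- 75
  class(traj_mixed) <- class(traj)
  m2 <- rate_map(sp, traj_mixed)
  expect_equal(sum(m2$counts), sum(sp > 300), tolerance = 5)
})

test_that("spatial information matches the closed forms", {
  # uniform map: score 0
  mk_map <- function(rate, occ = rep(10, 72)) {
    counts <- rate * occ
    structure(list(frame = "lab", n_bins = 72, bin_width = 5,
                   breaks = seq(0, 360, 5), occupancy = occ, counts = counts,
                   rate = rate, mean_rate = sum(counts) / sum(occ)),
              class = "rate_map")
  }
  expect_equal(spatial_information(mk_map(rep(4, 72))), 0)
  expect_equal(spatial_information(mk_map(rep(4, 72)), "bits_per_spike"), 0)
  # all rate in one bin, uniform occupancy: (1/72)*72*lambda*log2(72)
  one_hot <- mk_map(c(72 * 2, rep(0, 71)))
  expect_equal(one_hot$mean_rate, 2)
  expect_equal(spatial_information(one_hot), 2 * log2(72))
  expect_equal(spatial_information(one_hot, "bits_per_spike"), log2(72))
  # invariance to rotation of bin labels and to uniform time rescaling
  set.seed(2); r <- runif(72, 0, 8)
  expect_equal(spatial_information(mk_map(r)),
               spatial_information(mk_map(r[c(20:72, 1:19)])))
  expect_equal(spatial_information(mk_map(r, occ = rep(3, 72))),
               spatial_information(mk_map(r)))
  expect_error(spatial_information(mk_map(rep(0, 72))), "undefined")
})

test_that("landmark-frame information exceeds lab-frame for landmark-locked cells", {
  ses <- small_session(final_gain = 1.5, centers = c(60, 200),
                       session_laps = 25, noiseless = FALSE, seed = 19)
  er <- gaintrack:::epoch_time_range(ses$trajectory, ses$profile, 2:3)
  for (u in 1:2) {
    si_lm <- spatial_information(rate_map(ses$spikes[[u]], ses$trajectory,
                                          ses$profile, "landmark",
                                          time_range = er))
    si_lab <- spatial_information(rate_map(ses$spikes[[u]], ses$trajectory,
                                           ses$profile, "lab",
                                           time_range = er))
    expect_gt(si_lm, si_lab)
  }
})

test_that("peak rate recovers the simulated peak", {
  ses <- small_session(final_gain = 1, centers = 120, session_laps = 20,
                       noiseless = FALSE, peak_rate = 15, seed = 23)
  m <- rate_map(ses$spikes[[1]], ses$trajectory, ses$profile, "landmark")
  expect_equal(peak_rate(m), 15, tolerance = 0.25 * 15)
  expect_error(peak_rate(structure(list(rate = NA_real_), class = "rate_map")),
               "no occupied bins")
})

test_that("reliability is exact integer arithmetic over laps", {
  mk_field <- function(laps) {
    s <- data.frame(unit_id = 1L, start = 0, end = 40, center = 20 + laps * 360,
                    lap = laps, spike_count = 10L)
    class(s) <- c("sweep_set", "data.frame")
    structure(list(field_id = 1L, unit_id = 1L, sweeps = s),
              class = "place_field")
  }
  expect_identical(reliability(mk_field(0:19), 40), 0.5)
  expect_identical(reliability(mk_field(0:39), 40), 1)
  # duplicate sweeps on a lap count once
  expect_identical(reliability(mk_field(c(0, 0, 1)), 4), 0.5)
})

test_that("reliability recovers a simulated active lap range", {
  ses <- small_session(final_gain = 1, centers = 180, session_laps = 30,
                       seed = 29, active_lap_range = c(0, 27))
  flds <- detect_fields(ses)
  laps_run <- gaintrack:::frame_laps_run(ses$trajectory, ses$profile)
  rp <- reliability(flds[[1]], laps_run)
  expect_gt(rp, 0.9) # the high-reliability selection threshold
  expect_lte(rp, 1)
})

test_that("scaling factors equal the sweep gain for a landmark-locked field", {
  ses <- small_session(final_gain = 2, centers = 180, session_laps = 25,
                       seed = 37, epoch_laps = c(8, 7, 10, 0),
                       behavior_args = list(speed_sd = 0.5))
  f <- detect_fields(ses)[[1]]
  fp <- scaling_factor(f)
  gp <- f$sweeps$g_p
  # epoch-1 sweeps: f_p = 1 up to KDE discretization
  expect_equal(mean(fp[f$sweeps$epoch == 1]), 1, tolerance = 0.05)
  # constant-gain epoch-3 sweeps of a 40-degree landmark field have half
  # the lab extent, so f_p = 2
  e3 <- f$sweeps$epoch == 3
  expect_equal(median(fp[e3]), 2, tolerance = 0.15)
  # per-sweep agreement; the G = 2 geometry halves lab extents, so width
  # noise is amplified twofold relative to the unity-gain case
  expect_lt(median(abs(fp - gp)), 0.12)
  # ineligible without epoch-1 sweeps
  f2 <- f
  f2$sweeps <- f$sweeps[f$sweeps$epoch != 1, ]
  expect_error(scaling_factor(f2), "Epoch-1")
})

test_that("drift rate recovers injected drift with the right sign", {
  ses <- small_session(final_gain = 1, centers = 180, session_laps = 40,
                       seed = 41, drift_per_lab_lap = 0.5)
  f <- detect_fields(ses)[[1]]
  lab_laps <- gaintrack:::frame_laps_run(ses$trajectory)
  d <- drift_rate(f, lab_laps)
  expect_gt(d, 0.35); expect_lt(d, 0.6)
  # stationary field: drift ~ 0
  ses0 <- small_session(final_gain = 1, centers = 180, session_laps = 25,
                        seed = 43)
  d0 <- drift_rate(detect_fields(ses0)[[1]],
                   gaintrack:::frame_laps_run(ses0$trajectory))
  expect_lt(abs(d0), 0.1)
  # negative drift at a low gain stays negative
  sesn <- small_session(final_gain = 0.5, centers = 180, session_laps = 30,
                        seed = 47, drift_per_lab_lap = -0.3)
  dn <- drift_rate(detect_fields(sesn)[[1]],
                   gaintrack:::frame_laps_run(sesn$trajectory))
  expect_lt(dn, -0.15)
  # degenerate inputs
  f1 <- f; f1$sweeps <- f$sweeps[1, ]
  expect_error(drift_rate(f1, 10), "fewer than two")
  f3 <- f; f3$sweeps <- f$sweeps[1:3, ]
  expect_warning(drift_rate(f3, 10), "fewer than three")
})

test_that("ISI histograms keep only short intervals and find the theta comb", {
  # regular 100 ms train: single occupied bin at 100 ms
  h <- isi_histogram(seq(0, 10, by = 0.1))
  expect_equal(sum(h$counts > 0), 1)
  expect_lt(abs(h$mids[h$counts > 0] - 0.1), 0.011)
  # two spikes 0.6 s apart: empty
  expect_equal(sum(isi_histogram(c(0, 0.6))$counts), 0)
  # theta-locked simulated train (8 Hz, fixed preferred phase): ISI comb
  # with the dominant short-interval mode at one theta period, 125 ms
  lfp <- simulate_lfp(8, 1, 0, 300, 250)
  tm <- seq(0, 300, by = 0.02)
  traj <- angular_trajectory(tm, tm * 19.1, rep(25, length(tm)))
  spec <- place_cell_spec(frame = "lab", center = 180, width = 340,
                          peak_rate = 5, baseline_rate = 0,
                          theta_modulation_depth = 1, precession_span = 0)
  sp <- simulate_spikes(spec, traj, lfp = lfp, seed = 53)
  h2 <- isi_histogram(sp, bin_width = 0.01)
  sel <- h2$mids > 0.06
  mode_isi <- h2$mids[sel][which.max(h2$counts[sel])]
  expect_lt(abs(mode_isi - 0.125), 0.02)
})
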