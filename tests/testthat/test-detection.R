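# direct-convolution KDE oracle for small inputs
kde_oracle <- function(x, grid, bw) {
  vapply(grid, function(g) mean(dnorm(g, x, bw)), numeric(1))
}

test_that("firing_rate_analogue equals the direct-convolution oracle", {
  set.seed(1)
  x <- c(rnorm(40, 100, 4), rnorm(25, 160, 4))
  fra <- firing_rate_analogue(x)
  expect_equal(diff(fra$grid[1:2]), 0.5)
  ref <- kde_oracle(x, fra$grid, 8)
  # grid evaluation with linear binning: sup error well under 0.1% of peak
  expect_lt(max(abs(fra$density - ref)), 1e-3 * max(ref))
  # integrates to ~1 over the padded grid
  expect_equal(sum(fra$density) * 0.5, 1, tolerance = 1e-3)
  # two clusters 60 degrees apart resolve into two maxima near the means
  pk <- fra$grid[gaintrack:::local_maxima(fra$density)]
  expect_length(pk, 2)
  expect_lt(abs(pk[1] - mean(x[1:40])), 1)
  expect_lt(abs(pk[2] - mean(x[41:65])), 1)
})

test_that("single spikes and empty input behave as documented", {
  fra <- firing_rate_analogue(100)
  expect_equal(fra$grid[which.max(fra$density)], 100, tolerance = 0.5)
  e <- firing_rate_analogue(numeric(0))
  expect_length(e$grid, 0)
  expect_equal(nrow(detect_sweeps(e, numeric(0))), 0)
})

test_that("uniform spiking yields a flat analogue in the interior", {
  x <- seq(0, 3600, by = 1) # ten laps, evenly tiled
  fra <- firing_rate_analogue(x)
  interior <- fra$grid > 100 & fra$grid < 3500
  d <- fra$density[interior]
  expect_lt(sd(d) / mean(d), 0.1)
})

test_that("sweep size gates reject too-narrow and too-wide threshold regions", {
  # narrow: point cluster under a 1-degree kernel -> width ~4.3 < 5
  p_narrow <- detection_params(kde_bandwidth = 1)
  x <- rep(100, 50)
  expect_equal(nrow(detect_sweeps(firing_rate_analogue(x, p_narrow), x, p_narrow)), 0)
  # wide: same cluster under a 30-degree kernel -> width ~129 > 120
  p_wide <- detection_params(kde_bandwidth = 30)
  expect_equal(nrow(detect_sweeps(firing_rate_analogue(x, p_wide), x, p_wide)), 0)
  # default bandwidth: accepted
  sw <- detect_sweeps(firing_rate_analogue(x), x)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$center, 100, tolerance = 0.5)
  expect_equal(sw$spike_count, 50)
})

test_that("each pass of a simulated field becomes one sweep with a stable width", {
  ses <- small_session(final_gain = 1, centers = 180, session_laps = 20,
                       seed = 7,
                       behavior_args = list(pauses_per_lap = 0, speed_sd = 0.5))
  spa <- frame_spike_angles(ses, 1)
  sw <- detect_sweeps(firing_rate_analogue(spa), spa)
  expect_equal(nrow(sw), 20)
  expect_equal(sort(unique(sw$lap)), 0:19)
  w <- sw$end - sw$start
  # noiseless passes: widths consistent across laps (bout-speed variation
  # moves the outermost spikes slightly)
  expect_lt(sd(w) / mean(w), 0.06)
  expect_equal(mean(wrap_angle(sw$center)), 180, tolerance = 2)
  # geometric-midpoint invariant
  expect_equal(sw$center, (sw$start + sw$end) / 2)
})

test_that("clustering keeps the stable field and deletes strays", {
  mk_sweeps <- function(lap, center, n = 12) {
    s <- data.frame(unit_id = 1L, start = center - 25 + lap * 360,
                    end = center + 25 + lap * 360,
                    center = center + lap * 360, lap = lap, spike_count = n)
    class(s) <- c("sweep_set", "data.frame")
    s
  }
  stable <- do.call(rbind, lapply(0:24, mk_sweeps, center = 100))
  strays <- do.call(rbind, lapply(c(5, 17), mk_sweeps, center = 190, n = 5))
  sweeps <- rbind(stable, strays)
  class(sweeps) <- c("sweep_set", "data.frame")
  fields <- filter_and_cluster(sweeps)
  expect_length(fields, 1)
  expect_equal(nrow(fields[[1]]$sweeps), 25)
  expect_true(all(wrap_angle(fields[[1]]$sweeps$center) == 100))
  # two isolated sweeps alone cannot form a field
  expect_length(filter_and_cluster(rbind(mk_sweeps(1, 50), mk_sweeps(2, 50))), 0)
  # the spike-count gate deletes sparse sweeps before clustering
  sparse <- do.call(rbind, lapply(0:24, mk_sweeps, center = 100, n = 3))
  class(sparse) <- c("sweep_set", "data.frame")
  expect_length(filter_and_cluster(sparse), 0)
})

test_that("a unit with two fields 120 degrees apart is split correctly", {
  ses <- small_session(final_gain = 1.5, centers = c(60, 180),
                       session_laps = 25, seed = 13)
  # merge both cells into a single unit's spike train
  sp <- sort(c(ses$spikes[[1]], ses$spikes[[2]]))
  fr <- lab_to_frame(ses$trajectory, ses$profile)
  spa <- approx(ses$trajectory$time, fr$angle, sp)$y
  sw <- detect_sweeps(firing_rate_analogue(spa), spa)
  fields <- filter_and_cluster(sw)
  expect_length(fields, 2)
  ctrs <- sort(vapply(fields, field_center, numeric(1)))
  expect_lt(abs(ctrs[1] - 60), 5)
  expect_lt(abs(ctrs[2] - 180), 5)
})

test_that("clustering is order independent and matches the oracle", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(8:14, 1)
    sweeps <- data.frame(unit_id = 1L,
                         start = NA, end = NA,
                         center = sample(c(50, 55, 60, 170, 175, 300), n,
                                         replace = TRUE) + rnorm(n, 0, 3),
                         lap = sample(0:12, n, replace = TRUE),
                         spike_count = sample(3:10, n, replace = TRUE))
    sweeps$center <- sweeps$center + sweeps$lap * 360
    sweeps$start <- sweeps$center - 20
    sweeps$end <- sweeps$center + 20
    class(sweeps) <- c("sweep_set", "data.frame")
    got <- filter_and_cluster(sweeps)
    got_sets <- lapply(got, function(f) sort(f$sweeps$center))
    got_sets <- got_sets[order(vapply(got_sets, min, numeric(1)))]
    expect_equal(got_sets, cluster_oracle(sweeps))
    # permutation invariance
    perm <- sample(n)
    got_p <- filter_and_cluster(sweeps[perm, , drop = FALSE])
    got_p_sets <- lapply(got_p, function(f) sort(f$sweeps$center))
    got_p_sets <- got_p_sets[order(vapply(got_p_sets, min, numeric(1)))]
    expect_equal(got_p_sets, got_sets)
  }
})

test_that("merge_fields unions sweeps and validates units", {
  ses <- small_session(final_gain = 1, centers = c(80, 210), session_laps = 15,
                       seed = 3)
  f1 <- detect_fields(ses, 1)
  f2 <- detect_fields(ses, 2)
  f2[[1]]$field_id <- 2L
  f2[[1]]$unit_id <- f2[[1]]$sweeps$unit_id <- 1L # pretend same unit, split field
  fields <- c(f1, f2)
  merged <- merge_fields(fields, c(1, 2))
  expect_length(merged, 1)
  expect_equal(nrow(merged[[1]]$sweeps),
               nrow(f1[[1]]$sweeps) + nrow(f2[[1]]$sweeps))
  # self-merge is the identity
  again <- merge_fields(merged, merged[[1]]$field_id)
  expect_equal(nrow(again[[1]]$sweeps), nrow(merged[[1]]$sweeps))
  # different units refuse to merge
  g2 <- detect_fields(ses, 2)
  g2[[1]]$field_id <- 5L
  expect_error(merge_fields(c(f1, g2), c(1, 5)), "different units")
})

test_that("sweep gain is the mean of the gain at the sweep ends", {
  tm <- seq(0, 1200, by = 0.02)
  traj <- angular_trajectory(tm, tm * 18, rep(23.56, length(tm)))
  p <- gain_profile(epoch_laps = c(10, 10, 30, 0), final_gain = 1.4)
  mk <- function(start_lab, width_lab) {
    fr <- lab_to_frame(traj, p)$angle
    conv <- function(a) approx(traj$lab_angle, fr, a)$y
    s <- data.frame(unit_id = 1L, start = conv(start_lab),
                    end = conv(start_lab + width_lab), center = NA,
                    lap = 0L, spike_count = 10L)
    s$center <- (s$start + s$end) / 2
    class(s) <- c("sweep_set", "data.frame")
    s
  }
  # epoch 1: exactly 1; epoch 3: exactly G_final
  expect_equal(assign_sweep_gain(mk(5 * 360, 40), traj, p), 1)
  expect_equal(assign_sweep_gain(mk(25 * 360, 40), traj, p), 1.4)
  # ramp crossing: average of endpoint gains (1.0 and 1.2 -> 1.1)
  sw <- mk(10 * 360, 5 * 360)
  expect_equal(assign_sweep_gain(sw, traj, p), 1.1, tolerance = 1e-6)
})

test_that("field gain bins use the last sweep and flag overflow", {
  mk_field <- function(gains) {
    s <- data.frame(unit_id = 1L, start = 0, end = 40,
                    center = 20 + (seq_along(gains) - 1) * 360,
                    lap = seq_along(gains) - 1L, spike_count = 10L,
                    g_p = gains)
    class(s) <- c("sweep_set", "data.frame")
    structure(list(field_id = 1L, unit_id = 1L, sweeps = s),
              class = "place_field")
  }
  expect_equal(field_gain_bin(mk_field(c(1, 0.8, 0.5))), "(0,0.6]")
  expect_equal(field_gain_bin(mk_field(rep(1, 4))), "(0.9,1.1]")
  # the bin is the last sweep's gain, not the maximum
  expect_equal(field_gain_bin(mk_field(c(1, 1.9, 1.2))), "(1.1,1.4]")
  expect_warning(b <- field_gain_bin(mk_field(c(1, 2.6))), "overflow")
  expect_equal(b, "overflow")
})
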