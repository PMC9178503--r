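# Theta-band LFP processing: downsampling, zero-phase 6-12 Hz Butterworth
# band-pass, analytic-signal phase extraction, spike phases, and phase
# precession summaries over the normalized extent of sweeps.
#
# The band-pass is designed as a 15th-order Butterworth prototype but
# realized as cascaded second-order sections (biquads): at a 250 Hz rate
# the equivalent 30th-order transfer function is numerically unstable
# (rounded coefficients place poles outside the unit circle), while the
# biquad cascade is exact and stable. Each section is applied
# forward-backward, so the cascade is zero-phase by construction.

as_lfp <- function(time, value, rate, truth_phase = NULL) {
  structure(list(time = time, value = value, rate = rate,
                 truth_phase = truth_phase), class = "lfp")
}

#' @export
print.lfp <- function(x, ...) {
  cat("LFP:", length(x$value), "samples @", x$rate, "Hz (",
      round(max(x$time) - min(x$time), 1), "s )\n")
  invisible(x)
}

# odd (point-reflected) padding, filter through the SOS cascade with
# signal::filtfilt per section, trim
filtfilt_sos <- function(x, sos, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  for (s in sos) {
    xp <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), xp)
  }
  xp[(pad + 1):(pad + n)]
}

# Butterworth band-pass as second-order sections: analog lowpass
# prototype poles, lowpass-to-bandpass transform, bilinear transform,
# conjugate-pair pole grouping. Each section has zeros at z = +1 and
# z = -1; the overall gain is distributed evenly across sections.
butter_bandpass_sos <- function(order, low, high, fs) {
  stopifnot(order >= 1, low > 0, high > low, high < fs / 2)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  a <- bw * proto / 2
  s_poles <- c(a + sqrt(a^2 - w0^2), a - sqrt(a^2 - w0^2))
  K <- bw^order * Re((2 * fs)^order / prod(2 * fs - s_poles))
  zp <- (2 * fs + s_poles) / (2 * fs - s_poles)
  up <- zp[Im(zp) > 0]
  up <- up[order(Mod(up))]
  if (length(up) != order) stop("pole pairing failed; band too wide for SOS pairing")
  g <- abs(K)^(1 / order)
  lapply(up, function(P) {
    list(b = g * c(1, 0, -1), a = c(1, -2 * Re(P), Mod(P)^2))
  })
}

#' Downsample an LFP
#'
#' Anti-alias low-pass (8th-order Butterworth at 0.45 x target rate,
#' zero-phase) followed by resampling at the target rate. Ground-truth
#' phase, if present, is carried through.
#'
#' @param lfp An `lfp` object.
#' @param target_rate Target sampling rate, Hz (at most the source rate).
#' @return An `lfp` at `target_rate` with
#'   `ceiling(n * target / source)` samples.
#' @export
downsample_lfp <- function(lfp, target_rate = 250) {
  stopifnot(inherits(lfp, "lfp"))
  if (target_rate > lfp$rate) stop("target rate exceeds source rate")
  if (target_rate == lfp$rate) return(lfp)
  x <- lfp$value
  bf <- signal::butter(8, 0.9 * target_rate / lfp$rate, type = "low")
  xf <- filtfilt_sos(x, list(list(b = bf$b, a = bf$a)),
                     pad = min(length(x) - 1L, 3L * round(lfp$rate)))
  n_new <- ceiling(length(x) * target_rate / lfp$rate)
  t_new <- lfp$time[1] + (seq_len(n_new) - 1) / target_rate
  v_new <- stats::approx(lfp$time, xf, t_new, rule = 2)$y
  ph_new <- if (!is.null(lfp$truth_phase)) {
    stats::approx(lfp$time, lfp$truth_phase, t_new, rule = 2)$y
  }
  as_lfp(t_new, v_new, target_rate, ph_new)
}

#' Zero-phase theta band-pass filter
#'
#' Forward-backward Butterworth band-pass (design order 15, passband
#' 6-12 Hz), realized as cascaded second-order sections for numerical
#' stability. Zero group delay by construction.
#'
#' @param lfp An `lfp` object sampled at >= 100 Hz.
#' @param low,high Passband edges, Hz.
#' @param order Design order of the Butterworth prototype.
#' @return The filtered `lfp` (truth phase carried through).
#' @export
bandpass_theta <- function(lfp, low = 6, high = 12, order = 15) {
  stopifnot(inherits(lfp, "lfp"))
  if (lfp$rate < 100) stop("sampling rate must be at least 100 Hz")
  if (length(lfp$value) < 3 * lfp$rate) {
    stop("signal shorter than three filter settling times (3 s)")
  }
  sos <- butter_bandpass_sos(order, low, high, lfp$rate)
  v <- filtfilt_sos(lfp$value, sos, pad = 3L * round(lfp$rate))
  as_lfp(lfp$time, v, lfp$rate, lfp$truth_phase)
}

# analytic signal by the FFT (Hilbert) construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# unwrap a phase series given in degrees
unwrap_deg <- function(p) {
  if (length(p) < 2L) return(p)
  step <- ang_diff(p[-1], p[-length(p)])
  p[1] + c(0, cumsum(step))
}

# local maxima with a minimum index separation (greedy, tallest first)
peaks_min_sep <- function(y, min_sep) {
  cand <- local_maxima(y)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (p in cand) {
    if (!length(taken) || all(abs(taken - p) >= min_sep)) taken <- c(taken, p)
  }
  sort(taken)
}

#' Instantaneous theta phase
#'
#' Phase of the analytic signal of the filtered LFP, globally shifted so
#' the circular mean phase at local maxima of the filtered signal is 0
#' (phase 0 at theta peaks).
#'
#' @param lfp A band-passed `lfp` object.
#' @param peak_freq Upper bound on the oscillation frequency, used for the
#'   minimum peak separation (default 12 Hz).
#' @return List of class `phase_series`: `time`, `phase` (unwrapped,
#'   degrees, non-decreasing for a band-limited signal), `rate`.
#' @export
instantaneous_phase <- function(lfp, peak_freq = 12) {
  stopifnot(inherits(lfp, "lfp"))
  if (stats::sd(lfp$value) == 0) stop("constant signal; phase undefined")
  z <- analytic_signal(lfp$value)
  ph <- unwrap_deg(Arg(z) * 180 / pi)
  pk <- peaks_min_sep(lfp$value, min_sep = floor(lfp$rate / peak_freq))
  pk <- pk[pk > 1 & pk < length(ph)]
  if (length(pk)) {
    # parabolic sub-sample peak refinement avoids a quantization bias in
    # the mean peak phase (~1.5 deg at 250 Hz / 8 Hz)
    v <- lfp$value
    den <- v[pk - 1] - 2 * v[pk] + v[pk + 1]
    frac <- ifelse(den < 0, 0.5 * (v[pk - 1] - v[pk + 1]) / den, 0)
    pk_phase <- ph[pk] + frac * (ph[pk + 1] - ph[pk - 1]) / 2
    ph <- ph - ang_diff(circ_mean(wrap_angle(pk_phase)), 0)
  }
  structure(list(time = lfp$time, phase = ph, rate = lfp$rate),
            class = "phase_series")
}

#' Theta phase at spike times
#'
#' Linear interpolation on the unwrapped phase, wrapped afterward, so
#' spikes near cycle boundaries do not suffer +-180 degree artifacts.
#'
#' @param phases A `phase_series` from [instantaneous_phase()].
#' @param spike_times Spike times within the series' span, s.
#' @return Wrapped spike phases in `(-180, 180]`, degrees.
#' @export
spike_phases <- function(phases, spike_times) {
  stopifnot(inherits(phases, "phase_series"))
  if (any(spike_times < phases$time[1] |
            spike_times > phases$time[length(phases$time)])) {
    stop("spike times outside the phase series span")
  }
  wrap180(stats::approx(phases$time, phases$phase, spike_times)$y)
}

#' Phase precession histogram over normalized sweep extent
#'
#' For each spike attributable to a sweep, the normalized position is
#' `(spike angle - sweep start) / (sweep end - sweep start)`; counts are
#' accumulated over all sweeps into a 2-D histogram of normalized
#' position x theta phase. Spikes outside every sweep are ignored and
#' counted.
#'
#' @param sweeps A `sweep_set` (e.g. the sweeps of one or more fields).
#' @param spike_angles Spike locations in the sweeps' frame, degrees,
#'   unwrapped (same frame the sweeps were detected in).
#' @param phase_deg Wrapped theta phase per spike, degrees (from
#'   [spike_phases()]).
#' @param n_pos_bins,n_phase_bins Histogram resolution.
#' @return List: `counts` (`n_pos_bins` x `n_phase_bins` matrix),
#'   `pos_breaks`, `phase_breaks`, `x` and `phase` (per attributed
#'   spike), `n_outside`.
#' @export
precession_histogram <- function(sweeps, spike_angles, phase_deg,
                                 n_pos_bins = 20, n_phase_bins = 36) {
  stopifnot(length(spike_angles) == length(phase_deg))
  xs <- numeric(0); ps <- numeric(0)
  attributed <- rep(FALSE, length(spike_angles))
  if (nrow(sweeps)) for (k in seq_len(nrow(sweeps))) {
    s <- sweeps$start[k]; e <- sweeps$end[k]
    in_sw <- !attributed & spike_angles >= s & spike_angles <= e
    if (any(in_sw)) {
      xs <- c(xs, (spike_angles[in_sw] - s) / (e - s))
      ps <- c(ps, phase_deg[in_sw])
      attributed <- attributed | in_sw
    }
  }
  pos_breaks <- seq(0, 1, length.out = n_pos_bins + 1)
  phase_breaks <- seq(-180, 180, length.out = n_phase_bins + 1)
  counts <- matrix(0L, n_pos_bins, n_phase_bins)
  if (length(xs)) {
    bi <- pmin(pmax(findInterval(xs, pos_breaks, rightmost.closed = TRUE), 1L),
               n_pos_bins)
    bj <- pmin(pmax(findInterval(ps, phase_breaks, rightmost.closed = TRUE), 1L),
               n_phase_bins)
    for (i in seq_along(bi)) counts[bi[i], bj[i]] <- counts[bi[i], bj[i]] + 1L
  }
  list(counts = counts, pos_breaks = pos_breaks, phase_breaks = phase_breaks,
       x = xs, phase = ps, n_outside = sum(!attributed))
}

#' Fit a circular-linear precession slope
#'
#' Finds the slope (degrees of phase per unit normalized position) that
#' maximizes the resultant length of `phase - slope * x`, i.e. the
#' circular-linear regression slope of spike phase on normalized in-field
#' position. Precession corresponds to a negative slope.
#'
#' @param x Normalized positions in `[0, 1]`.
#' @param phase_deg Wrapped spike phases, degrees.
#' @param slope_range Length-2 search interval for the slope, degrees.
#' @return List: `slope` (deg per unit position), `offset` (deg, circular
#'   mean residual), `resultant` (mean resultant length at the optimum).
#' @export
fit_precession_slope <- function(x, phase_deg, slope_range = c(-720, 0)) {
  stopifnot(length(x) == length(phase_deg), length(x) >= 3)
  r <- pi / 180
  resultant <- function(s) Mod(mean(exp(1i * r * (phase_deg - s * x))))
  grid <- seq(slope_range[1], slope_range[2], by = 2)
  r0 <- vapply(grid, resultant, numeric(1))
  best <- grid[which.max(r0)]
  opt <- stats::optimize(resultant, lower = max(slope_range[1], best - 4),
                         upper = min(slope_range[2], best + 4), maximum = TRUE)
  s <- opt$maximum
  off <- Arg(mean(exp(1i * r * (phase_deg - s * x)))) / r
  list(slope = s, offset = off, resultant = opt$objective)
}
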