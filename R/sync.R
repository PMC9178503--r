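# Clock synchronization across unsynchronized acquisition systems.
#
# Two recordings of the same randomized TTL pulse train differ by an
# unknown offset (and possibly drift), so absolute onset times cannot be
# matched directly. The inter-pulse-interval sequences, however, are
# offset-invariant; they are aligned globally by Needleman-Wunsch dynamic
# programming, and the matched onset pairs are fed to a least-squares
# affine clock fit.

#' Sync pulse train
#'
#' @param onsets Pulse onset times, s, strictly increasing.
#' @param pulse_width Pulse duration, s.
#' @param check_gaps Require consecutive onsets to be separated by more
#'   than the pulse width (disable for corrupted trains with insertions).
#' @return List of class `pulse_train`.
#' @export
pulse_train <- function(onsets, pulse_width = 1, check_gaps = TRUE) {
  onsets <- as.numeric(onsets)
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    stop("onsets must be strictly increasing")
  }
  if (check_gaps && length(onsets) > 1 && any(diff(onsets) <= pulse_width)) {
    stop("overlapping pulses: onsets must be separated by more than pulse_width")
  }
  structure(list(onsets = onsets, pulse_width = pulse_width),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat("Pulse train:", length(x$onsets), "pulses")
  if (length(x$onsets) > 1) {
    cat(", mean interval", round(mean(diff(x$onsets)), 2), "s")
  }
  cat("\n")
  invisible(x)
}

#' Align two pulse trains by Needleman-Wunsch
#'
#' Globally aligns the inter-pulse-interval sequences of two trains.
#' Matching interval i of train a with interval j of train b scores
#' `-|da_i - db_j| / interval_tolerance`; gaps score `gap_penalty`.
#' Traceback prefers a match over a gap, then the gap consuming train a.
#' Matched intervals imply matched onset pairs (both endpoints of each
#' matched interval).
#'
#' @param a,b [pulse_train()] objects with at least 2 pulses each.
#' @param gap_penalty Score for leaving one interval unmatched.
#' @param interval_tolerance Interval discrepancy, s, that costs one unit
#'   of score.
#' @return List of class `alignment_result`: `pairs` (matrix of matched
#'   onset indices, strictly increasing in both columns),
#'   `interval_pairs`, `score`, `unmatched_a`, `unmatched_b` (pulse
#'   counts).
#' @export
align_pulse_trains <- function(a, b, gap_penalty = -1, interval_tolerance = 0.1) {
  stopifnot(inherits(a, "pulse_train"), inherits(b, "pulse_train"))
  if (length(a$onsets) < 2 || length(b$onsets) < 2) {
    stop("each train needs at least two pulses")
  }
  da <- diff(a$onsets); db <- diff(b$onsets)
  n <- length(da); m <- length(db)
  S <- -abs(outer(da, db, "-")) / interval_tolerance
  F <- matrix(-Inf, n + 1, m + 1)
  F[1, ] <- gap_penalty * (0:m)
  F[, 1] <- gap_penalty * (0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1, j + 1] <- max(F[i, j] + S[i, j],
                             F[i, j + 1] + gap_penalty,
                             F[i + 1, j] + gap_penalty)
    }
  }
  # traceback, preferring match, then gap in b (consume a), then gap in a
  i <- n; j <- m
  ia <- integer(0); ib <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(F[i + 1, j + 1], F[i, j] + S[i, j]))) {
      ia <- c(i, ia); ib <- c(j, ib)
      i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               isTRUE(all.equal(F[i + 1, j + 1], F[i, j + 1] + gap_penalty))) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  # onset pairs: both endpoints of every matched interval
  pa <- c(ia, ia + 1L); pb <- c(ib, ib + 1L)
  keep <- !duplicated(cbind(pa, pb))
  o <- order(pa[keep])
  pairs <- cbind(a = pa[keep][o], b = pb[keep][o])
  structure(list(pairs = pairs,
                 interval_pairs = cbind(a = ia, b = ib),
                 score = F[n + 1, m + 1],
                 unmatched_a = length(a$onsets) - nrow(pairs),
                 unmatched_b = length(b$onsets) - nrow(pairs)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("Pulse alignment:", nrow(x$pairs), "matched onsets, score",
      round(x$score, 2), "; unmatched", x$unmatched_a, "/", x$unmatched_b, "\n")
  invisible(x)
}

#' Fit an affine clock map from aligned pulse trains
#'
#' Least-squares line `b_time ~ offset + slope * a_time` over matched
#' onset pairs.
#'
#' @param result An [align_pulse_trains()] result.
#' @param a,b The aligned [pulse_train()] objects.
#' @return List of class `clock_map`: `offset` (s), `slope`,
#'   `residual_rms` (s), `n_pairs`.
#' @export
fit_clock_map <- function(result, a, b) {
  stopifnot(inherits(result, "alignment_result"))
  if (nrow(result$pairs) < 2) stop("need at least two matched pairs")
  ta <- a$onsets[result$pairs[, "a"]]
  tb <- b$onsets[result$pairs[, "b"]]
  fit <- stats::lm.fit(cbind(1, ta), tb)
  # one robust re-fit: spurious matches at train edges can leave gross
  # outlier pairs that leverage the line
  res <- fit$residuals
  tol <- max(6 * stats::mad(res), 1e-6)
  keep <- abs(res - stats::median(res)) <= tol
  if (sum(keep) >= 2 && any(!keep)) {
    fit <- stats::lm.fit(cbind(1, ta[keep]), tb[keep])
  }
  co <- fit$coefficients
  if (co[2] <= 0) stop("fitted slope is non-positive; alignment is unusable")
  structure(list(offset = unname(co[1]), slope = unname(co[2]),
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 n_pairs = nrow(result$pairs)),
            class = "clock_map")
}

#' @export
print.clock_map <- function(x, ...) {
  cat("Clock map: b = ", signif(x$offset, 6), " + ", signif(x$slope, 9),
      " * a  (rms ", signif(x$residual_rms * 1e3, 3), " ms, ",
      x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

#' Apply or invert a clock map
#'
#' @param times Times on clock a, s.
#' @param map A [fit_clock_map()] result.
#' @return Times on clock b, s.
#' @export
apply_clock_map <- function(times, map) {
  stopifnot(inherits(map, "clock_map"))
  map$offset + map$slope * times
}

#' @rdname apply_clock_map
#' @export
invert_clock_map <- function(map) {
  structure(list(offset = -map$offset / map$slope, slope = 1 / map$slope,
                 residual_rms = map$residual_rms / map$slope,
                 n_pairs = map$n_pairs),
            class = "clock_map")
}

#' Estimate feedback latency by cross-correlation
#'
#' Lag maximizing the normalized cross-correlation between an input
#' motion series (e.g. the tracked marker crown) and an output motion
#' series (e.g. the projected cue), with sign correction for
#' opposite-direction cue motion and parabolic sub-sample refinement.
#' Positive latency means the output lags the input.
#'
#' @param input_motion,output_motion Equal-length co-sampled series.
#' @param rate Sampling rate, Hz.
#' @param max_lag Largest |lag| searched, s.
#' @return Latency in seconds.
#' @export
estimate_latency <- function(input_motion, output_motion, rate, max_lag = 0.5) {
  stopifnot(length(input_motion) == length(output_motion), rate > 0)
  x <- input_motion - mean(input_motion)
  y <- output_motion - mean(output_motion)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("flat motion series; latency undefined")
  }
  L <- min(floor(max_lag * rate), length(x) - 2L)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- x[1:(length(x) - l)]; ys <- y[(1 + l):length(y)]
    } else {
      xs <- x[(1 - l):length(x)]; ys <- y[1:(length(y) + l)]
    }
    sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
  }, numeric(1))
  k <- which.max(abs(cc))
  refine <- 0
  if (k > 1 && k < length(cc)) {
    c0 <- abs(cc[k - 1]); c1 <- abs(cc[k]); c2 <- abs(cc[k + 1])
    denom <- c0 - 2 * c1 + c2
    if (denom < 0) refine <- 0.5 * (c0 - c2) / denom
  }
  (lags[k] + refine) / rate
}
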