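---
title: "Models and methods in gaintrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gaintrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaintrack` is a toolkit for analyzing closed-loop visual gain-manipulation
experiments with freely locomoting rodents on a circular track, together
with a synthetic-session generator that supplies ground truth for every
analysis stage. This vignette explains the models the package implements,
the tunable parameters and the reasoning behind their defaults, the
numerical choices, and what the simulator does and does not emulate.

## The experiment gain and reference frames

In these experiments a projected visual scene (polarizing landmarks, or a
ring of indistinguishable optic-flow stripes) rotates as a function of the
animal's own movement. The coupling is the *experiment gain*

$$G = \frac{\text{displacement of the animal in the cue frame}}
           {\text{displacement of the animal in the laboratory frame}},$$

so $G = 1$ means stationary cues, $G > 1$ cues that recede (rotate against
the running direction), and $G = 0$ cues that move with the animal. A
session is structured in four epochs, specified in laboratory-frame laps:
$G = 1$ throughout Epoch 1, a constant-per-lap linear ramp across Epoch 2,
$G = G_{final}$ through Epoch 3, and cues extinguished (gain bookkeeping
continuing) in Epoch 4. `gain_profile()` encodes this schedule; gain is a
function of lab distance, not time, because the ramp rate is fixed per lap
and session duration then depends on the final gain.

The cue-frame position is the path integral $\theta_f(t) = \theta_f(0) +
\int G \, d\theta_{lab}$. Because $G$ is piecewise linear in lab distance,
this integral has a closed form; `lab_to_frame()` evaluates that
antiderivative directly rather than accumulating a quadrature over
trajectory samples. The closed form is exact to machine precision even when
a sampling interval straddles an epoch boundary, which a trapezoid over
samples is not. Angles are kept in degrees throughout, with the unwrapped
(cumulative) representation canonical and laps indexed from 0.

The latency arithmetic is the product of three factors: the cue rotates at
the animal's angular speed times $|1-G|$, so a feedback latency $\tau$
displaces the rendered scene by $\omega \, |1-G| \, \tau$ degrees
(`latency_angular_error()`), which `arc_error()` converts to arc length at
the dome surface. At the protocol's typical values (about 20 deg/s angular
running speed, $G \in \{0, 2\}$, 100 ms latency, 2.3 m dome) this is about
2 degrees and about 4 cm.

## The synthetic-session generator

`simulate_session()` produces a trajectory, per-unit spike trains, a
theta-band LFP, and a randomized TTL pulse train, with the generating truth
retained. The defaults are the study conditions and are not tuned per
analysis:

* **Behavior** (`behavior_config()`): run bouts at speeds drawn from a
  normal distribution (mean 24.6 cm/s, s.d. 2.5, truncated below at
  5 cm/s), pause onsets as a Poisson process in distance (0.9 pauses per
  lap), pause durations gamma distributed (mean 8.8 s, shape 2), on a
  75 cm-radius track, sampled at 50 Hz as a camera-rate analogue. Means
  match the published behavioral summaries; the distribution families are
  simulator choices, since only the aggregates are published.
* **Place cells** (`place_cell_spec()`): a circular-Gaussian tuning curve
  in the owning frame (lab, landmark, or stripe), parameterized by its
  full width at 10% of peak so the generator's width definition matches
  the sweep detector's size definition. The rate is
  `baseline + (peak - baseline) * tuning`, multiplied by a theta factor
  `1 + depth * cos(phase - preferred(x))` whose preferred phase falls
  linearly from `+span/2` to `-span/2` across the field (phase
  precession). Place-specific firing is suppressed during immobility
  (speed at or below 5 cm/s) by default, reflecting the strong attenuation
  of place-field firing when rats stop; without this, a pause inside a
  field piles spikes at one position and distorts any location-based
  detector.
* **Spiking**: inhomogeneous Poisson by thinning against the envelope
  `peak * (1 + depth)`. A `noiseless = TRUE` mode instead emits spikes by
  deterministic time rescaling (one spike per unit of cumulative
  intensity); recovery tests use it so that what is measured is the
  method's bias, not Poisson variability.
* **LFP** (`simulate_lfp()`): a sinusoid at the theta frequency (8 Hz
  default, inside the 6-12 Hz band) plus white noise, with the exact
  instantaneous phase stored. The signal-to-noise ratio is quoted as
  amplitude over noise s.d.
* **Sync pulses** (`simulate_pulse_train()`): inter-onset intervals are a
  shifted exponential — a refractory floor of `pulse_width + 0.5` s plus
  an exponential component chosen so the mean interval is exactly the
  configured 10 s. Memoryless intervals make the alignment problem as
  hard as possible; the floor guarantees non-overlapping pulses.
  `corrupt_clock()` then applies offset, drift, jitter, drops, and
  spurious insertions, returning the true correspondence for scoring.

One RNG seed governs a session; per-unit sub-seeds are derived from it so
unit lists can change without perturbing other units.

What the simulator does **not** emulate: bursting and refractoriness,
interneurons, speed-dependent theta frequency, remapping dynamics beyond a
step active-lap range and linear drift, 2-D foraging, or measurement noise
in position tracking. Passing recovery tests therefore demonstrates the
correctness of the algorithms under the stated generative model, not their
performance on all features of real recordings.

## Sweep detection and field construction

Spike locations in the *unwrapped* cue frame are convolved with a Gaussian
kernel (s.d. 8 degrees) sampled on a 0.5-degree grid spanning the spike
range padded by three bandwidths. Each traversal of a field appears as its
own peak in unwrapped coordinates. The KDE is evaluated by linear binning
plus FFT convolution on the output grid itself; interpolating from a
power-of-two FFT grid (as generic density routines do) leaves flank
ripples of the order of 1e-3 of the peak that masquerade as spurious local
maxima.

For each local maximum, the sweep is the maximal contiguous interval where
the density exceeds 10% of *that peak's* height. The per-peak reading of
"10% of the maximum" was chosen over a global threshold because a global
maximum would erase legitimate low-rate fields of multi-field cells. A
local maximum whose interval contains a taller density point does not
define its own sweep — such shoulders belong to the taller peak's
structure; without this rule a tail shoulder's 10% region (10% of a tiny
height) can extend tens of degrees beyond the field. Intervals are then
gated to 5-120 degrees and overlapping intervals merged. Sweep centers are
geometric midpoints; a sweep spanning a lap boundary belongs to the lap
containing its center.

Filtering and clustering (`filter_and_cluster()`) follow two rules: a
sweep needs at least 4 spikes, and at least 3 other sweeps "in proximity"
— center within 15 degrees in wrapped cue coordinates and lap within a
15-lap window centered on the sweep's lap, excluding that lap itself. The
lap window is counted in cue-frame laps, since sweeps are defined in that
frame. Deletion is iterated to a fixpoint rather than applied in one
ordered pass, which makes the result provably independent of input order.
Surviving sweeps are partitioned into connected components of the
proximity graph; each component is a place field, and every member of a
component is automatically proximal to at least two others. Tie handling
when a sweep is near two candidate fields is therefore resolved by
connectivity. `merge_fields()` supports manual curation of over-segmented
fields; it deliberately skips invariant re-checks, since curation
overrides them.

Each sweep is mapped back through the trajectory to laboratory
coordinates (`annotate_sweeps()`), giving its lab-frame extent, its gain
`g_p` (mean of the gain at the sweep's start and end), and its epoch.

## Field metrics

* **Rate maps** use 72 bins of 5 degrees and all data where the animal's
  speed exceeds 5 cm/s; speed is taken from the trajectory, or derived by
  central differences smoothed over 0.25 s when absent (the estimator is
  otherwise too noisy to gate with).
* **Spatial information** is implemented exactly as the per-bin averaged
  score $\tfrac1B \sum_i \lambda_i \log_2(\lambda_i/\lambda)$ with zero
  and unoccupied bins contributing 0; this differs from the conventional
  occupancy-weighted bits-per-spike score, which is available separately
  under `definition = "bits_per_spike"`. The mean rate $\lambda$ is the
  occupancy-weighted grand mean (total spikes over total included time);
  the difference from the unweighted bin mean vanishes for uniform
  occupancy.
* **Reliability** `r_p` is the fraction of cue-frame laps with at least
  one sweep — exact integer arithmetic.
* **Scaling** `f_p` divides the mean Epoch-1 *lab-frame* sweep size by the
  sweep's lab-frame size. Lab-frame extents were chosen (over cue-frame)
  because the analysis quantifies scaling of fields in the laboratory
  frame, and only under that reading does `f_p` track `g_p` on the unity
  line. KDE smoothing inflates all widths by the same factor
  $\sqrt{1 + (bw/\sigma)^2}$, which cancels in the ratio.
* **Drift** `d_p` is the signed wrapped difference between circular means
  of the last three and first three sweep centers, per lab lap run.
  Signed, because drift can be negative at low gains and positive at high
  gains; positive is the running direction. Averaging the first/last three
  sweeps attenuates a constant drift rate by roughly (field span)/(laps
  run), about 7% on a 40-lap session.
* **ISI histograms** keep consecutive intervals up to 0.5 s.

## Theta phase and precession

The LFP path is: downsample to 250 Hz (zero-phase 8th-order Butterworth
anti-alias at 0.45 of the target rate, then resampling), band-pass 6-12 Hz,
analytic-signal phase, global shift so the circular mean phase at filtered
signal peaks is 0.

The band-pass honors a 15th-order Butterworth design but is realized as 15
cascaded biquads (second-order sections): the equivalent single
transfer-function realization is numerically unstable at 250 Hz — rounded
coefficients place poles outside the unit circle — while the cascade is
exact and stable. Poles are designed analytically (lowpass prototype,
lowpass-to-bandpass transform, bilinear transform) and paired
conjugate-by-conjugate; each section carries one zero at $z=+1$, one at
$z=-1$, and an equal share of the overall gain. Each section runs
forward-backward, so the cascade is zero-phase by construction; the
"stopband width 3 Hz" in the original description is treated as
descriptive of this design rather than an extra constraint, since a
Butterworth design is fully determined by order and passband. Signals are
padded by odd reflection before filtering to suppress edge transients.

Phase is the angle of the FFT-based analytic signal, unwrapped. Theta
peaks are detected with a minimum separation of one period at 12 Hz and
refined by parabolic interpolation before the zero-phase anchoring —
without sub-sample refinement the discrete peak grid biases the anchor by
about 1.5 degrees at 250 Hz. Spike phases are interpolated on the
*unwrapped* phase and wrapped afterwards, avoiding ±180-degree artifacts
near cycle boundaries.

Precession summaries normalize each spike's position to its sweep's
extent and histogram position against phase. The ridge is quantified by a
circular-linear fit: the slope maximizing the mean resultant of
`phase - slope * x`, searched on a 2-degree grid over [-720, 0] and
refined by golden-section optimization. Because detected sweeps are wider
than the generating field by the KDE inflation factor, the fitted slope
overestimates the generating span by that factor; recovery tests use a
100-degree field, where the inflation is about 6%.

## Clock synchronization and latency

Two recordings of the same pulse train differ by an unknown offset (and
drift), so the *inter-pulse-interval* sequences are aligned instead of
absolute times: global alignment by Needleman-Wunsch dynamic programming,
match score $-|\Delta \text{interval}|/\text{tolerance}$ (tolerance
0.1 s), gap penalty $-1$, traceback preferring matches over gaps. The
scoring scheme is a documented package default, validated by recovery
tests; on small instances the DP score equals an exhaustive search over
all monotone matchings. Matched intervals yield matched onset pairs, which
feed a least-squares affine clock fit with one robust re-fit pass that
discards gross outlier pairs (residuals beyond six times the median
absolute deviation) — spurious edge matches otherwise leverage the line.
A once-per-lap hall-effect backup pulse is handled as just another pulse
train.

Feedback latency is the lag maximizing the normalized cross-correlation of
an input motion series (tracked head markers) and an output motion series
(the projected cue), with sign correction for opposite-direction cue
motion and parabolic sub-sample refinement; this recovers a 105 ms delay
to sub-frame accuracy at camera rates from 30 to 90 Hz.

## Degenerate inputs and numerical conventions

Empty spike sets produce empty analogues and zero sweeps; fields with
fewer than two sweeps have undefined drift (error) and two to five sweeps
use overlapping end-sets with a warning; rate maps with no samples above
the speed gate are a defined error, as is spatial information of a
zero-rate map; a constant LFP has undefined phase (error); aligning trains
with fewer than two pulses is an error; gains are undefined at negative
lab distances (error). Wrapped angles live in [0, 360), signed differences
in (-180, 180], and gain bins default to five ranges with a lowest bin of
0-0.6 (the remaining edges, 0.9/1.1/1.4/2.0, are package defaults; only
the lowest range is fixed by the protocol description).

## Problem sizes in the test suite

The recovery tests simulate 40-lap sessions with five landmark-locked
cells for field recovery and scaling, 20-40-lap single-cell sessions for
reliability, drift, and precession, 60 s LFP segments for phase accuracy,
50 corrupted 600 s pulse trains for clock recovery, and 60 s motion traces
at five camera rates for latency. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays quick to run.

## Known limitations

Sweep widths inherit the KDE bandwidth: detected extents are inflated
relative to generating fields, so absolute width estimates are
bandwidth-dependent even though width *ratios* (scaling) are not. The
detector assumes unidirectional running; backtracking through a field
within a lap would merge passes. The clock fit assumes an affine
relation; thermal drift curvature over very long sessions is not modeled.
Manual curation (`merge_fields()`) is exposed but no graphical review
tool is provided.
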