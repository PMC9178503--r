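Package: gaintrack
Title: Analysis Toolkit for Closed-Loop Gain-Manipulation Experiments on
    Circular Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core for virtual-reality gain-recalibration
    experiments with freely locomoting rodents on a circular track.
    Models the experiment gain and the laboratory/landmark/stripe
    reference-frame transforms, simulates complete synthetic sessions
    (run/pause trajectories, inhomogeneous-Poisson place-cell spike
    trains with theta modulation and phase precession, theta-band LFP,
    randomized TTL sync pulses), detects place-field sweeps by kernel
    density estimation and clusters them into fields, computes field
    metrics (spatial information, reliability, scaling, drift, ISI
    histograms), extracts theta phase and precession summaries, and
    synchronizes unsynchronized clocks by Needleman-Wunsch alignment of
    pulse trains with cross-correlation latency estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
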