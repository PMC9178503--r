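# Session I/O: a session is a directory of plain-text files
# (trajectory.csv, spikes_unit<k>.csv, lfp.csv, pulses_a.csv, truth.json,
# profile.yaml). All tables are RFC-4180 CSV with headers; configs are
# YAML; results are JSON. Round trips are lossless.

SESSION_FORMAT_VERSION <- "1"

#' Write a gain profile to YAML
#'
#' @param profile A [gain_profile()].
#' @param path Output file path.
#' @export
write_gain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gain_profile"))
  yaml::write_yaml(list(epoch_laps = profile$epoch_laps,
                        final_gain = profile$final_gain,
                        cue = profile$cue,
                        landmarks_visible_epochs = which(profile$landmarks_visible)),
                   path)
  invisible(path)
}

#' Read a gain profile from YAML
#'
#' @param path YAML file written by [write_gain_profile()].
#' @return A [gain_profile()].
#' @export
read_gain_profile <- function(path) {
  y <- yaml::read_yaml(path)
  vis <- rep(FALSE, 4)
  vis[unlist(y$landmarks_visible_epochs)] <- TRUE
  gain_profile(epoch_laps = unlist(y$epoch_laps), final_gain = y$final_gain,
               cue = y$cue, landmarks_visible = vis)
}

#' Write a trajectory to CSV
#'
#' Columns `time_s`, `lab_angle_deg_unwrapped`, `speed_cm_s`.
#'
#' @param traj An [angular_trajectory()].
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "angular_trajectory"))
  utils::write.csv(data.frame(time_s = traj$time,
                              lab_angle_deg_unwrapped = traj$lab_angle,
                              speed_cm_s = traj$speed),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' @param path CSV with columns `time_s`, `lab_angle_deg_unwrapped`, and
#'   optionally `speed_cm_s`. Extra columns are preserved with a warning.
#' @param track_radius Track radius, cm.
#' @return An [angular_trajectory()].
#' @export
read_trajectory <- function(path, track_radius = 75) {
  d <- utils::read.csv(path)
  need <- c("time_s", "lab_angle_deg_unwrapped")
  if (!all(need %in% names(d))) {
    stop("trajectory file lacks required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  extra <- setdiff(names(d), c(need, "speed_cm_s"))
  traj <- angular_trajectory(d$time_s, d$lab_angle_deg_unwrapped,
                             if ("speed_cm_s" %in% names(d)) d$speed_cm_s,
                             track_radius = track_radius)
  if (length(extra)) {
    warning("preserving extra trajectory columns: ", paste(extra, collapse = ", "))
    for (col in extra) traj[[col]] <- d[[col]]
  }
  traj
}

#' Write a synthetic session to a directory
#'
#' @param session A `synthetic_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(session$trajectory, file.path(dir, "trajectory.csv"))
  for (k in seq_along(session$spikes)) {
    utils::write.csv(data.frame(time_s = session$spikes[[k]]),
                     file.path(dir, sprintf("spikes_unit%d.csv", k)),
                     row.names = FALSE)
  }
  if (!is.null(session$lfp)) {
    utils::write.csv(data.frame(time_s = session$lfp$time,
                                value = session$lfp$value),
                     file.path(dir, "lfp.csv"), row.names = FALSE)
  }
  utils::write.csv(data.frame(onset_s = session$pulses$onsets),
                   file.path(dir, "pulses_a.csv"), row.names = FALSE)
  write_gain_profile(session$profile, file.path(dir, "profile.yaml"))
  truth <- list(
    format_version = SESSION_FORMAT_VERSION,
    seed = session$seed,
    track_radius = attr(session$trajectory, "track_radius"),
    lfp_rate = if (!is.null(session$lfp)) session$lfp$rate,
    n_units = length(session$spikes),
    cells = lapply(session$cells, function(s) {
      s[!vapply(s, is.null, logical(1))]
    })
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session directory
#'
#' @param dir Directory written by [write_session()] (or assembled by
#'   hand with the same layout). `trajectory.csv` is required.
#' @return A `synthetic_session` (truth restored when `truth.json` is
#'   present; LFP truth phase is not persisted).
#' @export
read_session <- function(dir) {
  tf <- file.path(dir, "trajectory.csv")
  if (!file.exists(tf)) stop("missing trajectory.csv in ", dir)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  radius <- if (!is.null(truth$track_radius)) truth$track_radius else 75
  traj <- read_trajectory(tf, track_radius = radius)
  pf <- file.path(dir, "profile.yaml")
  profile <- if (file.exists(pf)) read_gain_profile(pf) else gain_profile()
  spike_files <- sort(list.files(dir, pattern = "^spikes_unit[0-9]+\\.csv$",
                                 full.names = TRUE))
  ord <- order(as.integer(sub(".*spikes_unit([0-9]+)\\.csv$", "\\1", spike_files)))
  spike_files <- spike_files[ord]
  spikes <- lapply(spike_files, function(f) utils::read.csv(f)$time_s)
  names(spikes) <- paste0("unit", seq_along(spikes))
  lfp <- NULL
  lf <- file.path(dir, "lfp.csv")
  if (file.exists(lf)) {
    d <- utils::read.csv(lf)
    rate <- if (!is.null(truth$lfp_rate)) truth$lfp_rate else
      round(1 / stats::median(diff(d$time_s)))
    lfp <- as_lfp(d$time_s, d$value, rate)
  }
  pulses <- NULL
  puf <- file.path(dir, "pulses_a.csv")
  if (file.exists(puf)) {
    pulses <- pulse_train(utils::read.csv(puf)$onset_s, check_gaps = FALSE)
  }
  cells <- list()
  if (!is.null(truth$cells) && length(truth$cells)) {
    raw <- truth$cells
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    cells <- lapply(raw, function(s) {
      args <- lapply(as.list(s), function(v) if (is.list(v)) unlist(v) else v)
      args <- args[names(args) %in% names(formals(place_cell_spec))]
      args <- args[!vapply(args, function(v) length(v) == 0 || all(is.na(v)),
                           logical(1))]
      do.call(place_cell_spec, args)
    })
    names(cells) <- NULL
  }
  structure(list(trajectory = traj, spikes = spikes, lfp = lfp, pulses = pulses,
                 profile = profile, cells = cells,
                 seed = if (!is.null(truth$seed)) truth$seed else NA_integer_),
            class = "synthetic_session")
}
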