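#' Construct a single-unit record
#'
#' @param unit_id Unique identifier (character).
#' @param region `"dCA1"` or `"mOFC"`.
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing and non-negative.
#' @param trough_to_peak Waveform trough-to-peak latency, ms.
#' @param acg_tau_rise Autocorrelogram rise time constant, ms.
#' @param duration_s Recording duration used to derive the mean rate.
#' @param cell_type Optional; derived from the two metrics when `NULL`.
#' @return A `gs_unit` object.
#' @export
gs_unit <- function(unit_id, region, spike_times, trough_to_peak,
                    acg_tau_rise, duration_s, cell_type = NULL) {
  region <- match.arg(region, c("dCA1", "mOFC"))
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && (any(spike_times < 0) || is.unsorted(spike_times)))
    stop("spike_times must be sorted and non-negative")
  if (is.null(cell_type))
    cell_type <- classify_cell_type(trough_to_peak, acg_tau_rise)
  structure(list(
    unit_id = as.character(unit_id),
    region = region,
    spike_times = spike_times,
    trough_to_peak = trough_to_peak,
    acg_tau_rise = acg_tau_rise,
    mean_rate = length(spike_times) / duration_s,
    duration_s = duration_s,
    cell_type = cell_type
  ), class = "gs_unit")
}

#' Construct a 50-Hz head-position track
#'
#' Velocity is derived once here (centered finite differences smoothed with
#' a 5-sample moving average, see [compute_velocity()]) so that every
#' downstream stage shares a single speed definition.
#'
#' @param times Sample times in seconds (uniform at 50 Hz).
#' @param x,y Head coordinates in cm, maze-centered frame.
#' @return A `gs_track` object with a `velocity` field in cm/s.
#' @export
gs_track <- function(times, x, y) {
  stopifnot(length(times) == length(x), length(x) == length(y))
  if (length(times) >= 2) {
    dt <- diff(times)
    if (any(abs(dt - 1 / TRACK_FS) > 1e-6))
      stop("track must be uniformly sampled at 50 Hz")
  }
  tr <- structure(list(times = as.numeric(times), x = as.numeric(x),
                       y = as.numeric(y), fs = TRACK_FS),
                  class = "gs_track")
  tr$velocity <- if (length(times) >= 3) compute_velocity(tr) else
    rep(0, length(times))
  tr
}

#' Construct an LFP signal
#'
#' @param samples Numeric vector, microvolts, sampled at 1,000 Hz.
#' @param region Region label.
#' @param fs Sampling rate; must be 1,000 Hz.
#' @return A `gs_lfp` object.
#' @export
gs_lfp <- function(samples, region, fs = LFP_FS) {
  if (fs != LFP_FS) stop("LFP must be sampled at 1,000 Hz")
  if (any(!is.finite(samples))) stop("LFP samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, region = region),
            class = "gs_lfp")
}

#' Assemble a recording session
#'
#' Container for one daily session: unit spike trains with region and
#' cell-type labels, the position track, one LFP channel per region, the two
#' rewarded goal locations of the current and previous day, learning-trial
#' windows, and the pre-/post-probe windows.
#'
#' @param session_id Identifier.
#' @param units List of [gs_unit()] objects.
#' @param track A [gs_track()].
#' @param lfp Named list of [gs_lfp()] objects, one per region.
#' @param goals_current,goals_previous 2x2 matrices, one `(x, y)` row per
#'   rewarded location, cm.
#' @param trials Data frame with `start_s`, `end_s`; non-overlapping,
#'   ordered.
#' @param probes Named list with `pre` and `post` two-element `c(start, end)`
#'   windows, or `NULL`.
#' @param start_box Rectangle `c(xmin, xmax, ymin, ymax)` for the start box.
#' @param maze_radius Arena radius in cm (default 75, a 150-cm board).
#' @return A `gs_session` object.
#' @export
gs_session <- function(session_id, units, track, lfp, goals_current,
                       goals_previous, trials, probes = NULL,
                       start_box = c(-80, -60, -15, 15), maze_radius = 75) {
  goals_current <- as_goal_matrix(goals_current)
  goals_previous <- as_goal_matrix(goals_previous)
  trials <- as.data.frame(trials)
  stopifnot(all(c("start_s", "end_s") %in% names(trials)))
  if (nrow(trials) > 1) {
    if (is.unsorted(trials$start_s)) stop("trials must be ordered")
    if (any(trials$start_s[-1] < trials$end_s[-nrow(trials)]))
      stop("trials must be non-overlapping")
  }
  structure(list(
    session_id = as.character(session_id),
    units = units, track = track, lfp = lfp,
    goals_current = goals_current, goals_previous = goals_previous,
    trials = trials, probes = probes, epochs = NULL,
    start_box = start_box, maze_radius = maze_radius
  ), class = "gs_session")
}

as_goal_matrix <- function(g) {
  g <- matrix(as.numeric(unlist(g)), ncol = 2, byrow = !is.matrix(g))
  if (nrow(g) != 2) stop("exactly two goals per goal set are required")
  colnames(g) <- c("x", "y")
  g
}

#' @export
print.gs_session <- function(x, ...) {
  cat(sprintf("<gs_session '%s'>\n", x$session_id))
  cat(sprintf("  units: %d (%s)\n", length(x$units),
              paste(sprintf("%s=%d", names(table(vapply(x$units, `[[`,
                    "", "region")))[],
                    table(vapply(x$units, `[[`, "", "region"))),
                    collapse = ", ")))
  cat(sprintf("  track: %d samples (%.1f s at %d Hz)\n",
              length(x$track$times),
              diff(range(x$track$times)), x$track$fs))
  cat(sprintf("  lfp regions: %s\n", paste(names(x$lfp), collapse = ", ")))
  cat(sprintf("  trials: %d\n", nrow(x$trials)))
  invisible(x)
}

#' Validate all session invariants
#'
#' Checks spike-time ordering, track sampling, LFP rate and finiteness,
#' trial ordering, goal-set cardinality and (optionally) the goal placement
#' constraints used when goals are generated: more than 50 cm between
#' same-day goals and more than 20 cm from the maze edge.
#'
#' @param session A `gs_session`.
#' @param check_goal_placement Also enforce placement constraints.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_session <- function(session, check_goal_placement = TRUE) {
  stopifnot(inherits(session, "gs_session"))
  for (u in session$units) {
    if (length(u$spike_times) &&
        (is.unsorted(u$spike_times) || any(u$spike_times < 0)))
      stop(sprintf("unit %s: spike times unsorted or negative", u$unit_id))
    if (abs(u$mean_rate - length(u$spike_times) / u$duration_s) > 1e-9)
      stop(sprintf("unit %s: mean_rate inconsistent with spike count",
                   u$unit_id))
  }
  tr <- session$track
  if (length(tr$times) >= 2 &&
      any(abs(diff(tr$times) - 1 / TRACK_FS) > 1e-6))
    stop("track sampling deviates from 50 Hz")
  if (any(tr$velocity < 0)) stop("velocity must be non-negative")
  for (l in session$lfp) {
    if (l$fs != LFP_FS) stop("LFP fs must be 1,000 Hz")
    if (any(!is.finite(l$samples))) stop("LFP contains non-finite samples")
  }
  for (g in list(session$goals_current, session$goals_previous))
    if (nrow(g) != 2) stop("exactly two goals per goal set")
  if (check_goal_placement) {
    for (g in list(session$goals_current, session$goals_previous)) {
      if (sqrt(sum((g[1, ] - g[2, ])^2)) <= 50)
        stop("same-day goals must be more than 50 cm apart")
      if (any(sqrt(rowSums(g^2)) > session$maze_radius - 20))
        stop("goals must be more than 20 cm from the maze edge")
    }
  }
  invisible(TRUE)
}

#' Write a session to a directory of plain-text files
#'
#' Layout: `session.json` (identifiers, goals, trials, probes, unit
#' metadata), `spikes.csv` (`unit_id,time_s`), `track.csv`
#' (`time_s,x_cm,y_cm`) and `lfp.csv` (one column per region). Chosen for
#' diff-ability and zero binary dependencies.
#'
#' @param session A `gs_session`.
#' @param path Output directory (created if missing).
#' @return Invisibly `path`.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    session_id = session$session_id,
    goals_current = unname(session$goals_current),
    goals_previous = unname(session$goals_previous),
    trials = session$trials,
    probes = session$probes,
    start_box = session$start_box,
    maze_radius = session$maze_radius,
    track_fs = session$track$fs,
    lfp_fs = LFP_FS,
    units = data.frame(
      unit_id = vapply(session$units, `[[`, "", "unit_id"),
      region = vapply(session$units, `[[`, "", "region"),
      trough_to_peak = vapply(session$units, `[[`, 0, "trough_to_peak"),
      acg_tau_rise = vapply(session$units, `[[`, 0, "acg_tau_rise"),
      duration_s = vapply(session$units, `[[`, 0, "duration_s"),
      cell_type = vapply(session$units, `[[`, "", "cell_type"),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  spikes <- do.call(rbind, lapply(session$units, function(u)
    if (length(u$spike_times))
      data.frame(unit_id = u$unit_id, time_s = u$spike_times) else NULL))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), time_s = numeric(0))
  write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = session$track$times,
                       x_cm = session$track$x, y_cm = session$track$y),
            file.path(path, "track.csv"), row.names = FALSE)
  lfp_df <- as.data.frame(lapply(session$lfp, `[[`, "samples"))
  names(lfp_df) <- names(session$lfp)
  write.csv(lfp_df, file.path(path, "lfp.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session previously written by [write_session()]
#'
#' Round-trip identity: reading a written session reproduces every numeric
#' field to full precision.
#'
#' @param path Session directory.
#' @return A `gs_session`.
#' @export
read_session <- function(path) {
  need <- c("session.json", "spikes.csv", "track.csv", "lfp.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop(sprintf("session directory '%s' is missing stream(s): %s",
                 path, paste(missing, collapse = ", ")))
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  spikes <- read.csv(file.path(path, "spikes.csv"),
                     colClasses = c("character", "numeric"))
  track_df <- read.csv(file.path(path, "track.csv"))
  lfp_df <- read.csv(file.path(path, "lfp.csv"))
  track <- gs_track(track_df$time_s, track_df$x_cm, track_df$y_cm)
  lfp <- lapply(names(lfp_df), function(rg) gs_lfp(lfp_df[[rg]], rg))
  names(lfp) <- names(lfp_df)
  um <- meta$units
  units <- lapply(seq_len(nrow(um)), function(i) {
    st <- spikes$time_s[spikes$unit_id == um$unit_id[i]]
    gs_unit(um$unit_id[i], um$region[i], sort(st), um$trough_to_peak[i],
            um$acg_tau_rise[i], um$duration_s[i], um$cell_type[i])
  })
  probes <- meta$probes
  if (!is.null(probes)) probes <- lapply(probes, as.numeric)
  s <- gs_session(meta$session_id, units, track, lfp,
                  matrix(unlist(meta$goals_current), ncol = 2,
                         byrow = is.list(meta$goals_current)),
                  matrix(unlist(meta$goals_previous), ncol = 2,
                         byrow = is.list(meta$goals_previous)),
                  meta$trials, probes,
                  as.numeric(meta$start_box), meta$maze_radius)
  s
}
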