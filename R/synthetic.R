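#' Configuration for the synthetic session generator
#'
#' Defaults mirror the recorded task: a 150-cm cheeseboard with a start box
#' at the left edge, two rewarded goals per day placed more than 50 cm
#' apart (and more than 50 cm from the previous day's goals, more than
#' 20 cm from the edge), 40 learning trials whose path length shortens
#' along a piecewise-linear schedule with a breakpoint near trial 10, and
#' pre-/post-probe foraging periods. LFP knobs control theta frequency,
#' inter-regional phase-lag jitter (PLV), theta-phase modulation of the
#' gamma envelope (PAC) and ripple-burst rate at goals; spiking knobs
#' control place/goal tuning, theta locking, planted short-latency pairs
#' and planted assemblies.
#'
#' @param seed Master seed; a fixed seed makes the session bit-reproducible.
#' @param ... Overrides of any default listed below.
#' @return A `gs_synth_config` list.
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    maze_radius = 75,
    start_box = c(-80, -60, -15, 15),
    goals_current = matrix(c(40, 20, -30, -35), 2, byrow = TRUE),
    goals_previous = matrix(c(-40, 30, 25, -40), 2, byrow = TRUE),
    n_trials = 40,
    breakpoint_trial = 10,
    path_pre_slope = -80,    # cm per trial before the breakpoint
    path_post_slope = 0,     # cm per trial after it
    path_floor = 400,        # asymptotic path length, cm
    dwell_s = 2.5,           # goal dwell per visit, s
    inter_trial_s = 2,
    run_speed = 22,          # nominal running speed, cm/s
    pre_probe_s = 1500,
    post_probe_s = 1500,
    # LFP
    theta_hz = 8,
    gamma_hz = c(low = 40, high = 75),
    theta_amp = 50, gamma_amp = 15, noise_sd = 10,
    pac_depth = 0.6, pac_phase = 0,
    plv_lag = pi / 6, plv_lag_jitter = 0.2,
    swr_rate_goal = 0.2,     # events/s of immobile at-goal time
    # spiking
    n_place = c(dCA1 = 12, mOFC = 2),
    n_goal = c(dCA1 = 3, mOFC = 8),
    n_interneuron = c(dCA1 = 3, mOFC = 3),
    goal_remap_fraction = 0.6,
    place_sigma = 12, place_peak = 8, baseline_rate = 0.3,
    interneuron_rate = 12,
    theta_locked_fraction = 0.5, theta_kappa = 1.5,
    ccg_pairs = NULL,        # data frame: ref, target, latency_ms, excess_p
    assemblies = NULL,       # list of integer member vectors
    assembly_rate = 0.3      # latent co-activation events/s
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "gs_synth_config")
}

#' Piecewise-linear target path length per trial
#'
#' @param cfg A [synth_config()].
#' @return Numeric vector of `n_trials` target path lengths, cm.
#' @export
path_length_schedule <- function(cfg) {
  t <- seq_len(cfg$n_trials)
  tau <- cfg$breakpoint_trial
  cfg$path_floor + cfg$path_pre_slope * (pmin(t, tau) - tau) +
    cfg$path_post_slope * pmax(t - tau, 0)
}

# slowly varying positional wobble: keeps realized path lengths close to
# the polyline length (white jitter would inflate them)
smooth_jitter <- function(n, sd, span = 25) {
  if (n <= span) return(matrix(0, n, 2))
  apply(matrix(rnorm(2 * (n + span)), ncol = 2), 2, function(z) {
    f <- as.numeric(stats::filter(z, rep(1 / span, span), sides = 1))
    f <- f[(span + 1):(n + span)]
    f * sd / max(sd(f), 1e-9)
  })
}

# polyline traversal at ~constant speed, 50 Hz
traverse <- function(waypoints, speed, fs = TRACK_FS, jitter = 0.5) {
  seg <- diff(waypoints)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  n <- max(2, round(total / speed * fs))
  d <- seq(0, total, length.out = n)
  cum <- c(0, cumsum(seg_len))
  si <- pmin(findInterval(d, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (d - cum[si]) / pmax(seg_len[si], 1e-9)
  pos <- waypoints[si, , drop = FALSE] + seg[si, , drop = FALSE] * frac
  pos + smooth_jitter(n, jitter)
}

dwell_at <- function(point, dur_s, fs = TRACK_FS, jitter = 0.25) {
  n <- max(1, round(dur_s * fs))
  cbind(point[1] + smooth_jitter(n, jitter)[, 1],
        point[2] + smooth_jitter(n, jitter)[, 2])
}

random_point <- function(radius) {
  repeat {
    p <- runif(2, -radius, radius)
    if (sum(p^2) <= radius^2) return(p)
  }
}

# waypoint list for one learning trial hitting both goals with a target
# path length; detour waypoints are inserted until the polyline is long
# enough
trial_waypoints <- function(cfg, target_len) {
  exit_pt <- c(cfg$start_box[2], 0)
  g <- cfg$goals_current
  wp <- rbind(exit_pt, g[1, ], g[2, ], exit_pt)
  polyline_len <- function(w) sum(sqrt(rowSums(diff(w)^2)))
  guard <- 0
  while (polyline_len(wp) < target_len && guard < 200) {
    guard <- guard + 1
    seg <- sample(nrow(wp) - 1, 1)
    mid <- (wp[seg, ] + wp[seg + 1, ]) / 2
    det <- mid + runif(2, -35, 35)
    r <- sqrt(sum(det^2))
    if (r > cfg$maze_radius - 8) det <- det * (cfg$maze_radius - 8) / r
    wp <- rbind(wp[1:seg, , drop = FALSE], det,
                wp[(seg + 1):nrow(wp), , drop = FALSE])
  }
  wp
}

#' Generate the position track and trial windows
#'
#' Builds pre-probe foraging, `n_trials` learning trials (start-box exit,
#' both goals visited with a dwell, return; path length following
#' [path_length_schedule()]) and post-probe foraging, all at 50 Hz.
#'
#' @param cfg A [synth_config()].
#' @return List with `track` ([gs_track()]), `trials` (data frame),
#'   `probes` (list `pre`, `post`).
#' @export
generate_trajectory <- function(cfg) {
  set.seed(cfg$seed)
  if (sqrt(sum((cfg$goals_current[1, ] - cfg$goals_current[2, ])^2)) <= 50)
    stop("unreachable goal configuration: goals too close")
  fs <- TRACK_FS
  lens <- path_length_schedule(cfg)
  segs <- list(); trial_rows <- NULL
  box_center <- c(mean(cfg$start_box[1:2]), mean(cfg$start_box[3:4]))

  forage <- function(dur_s) {
    pts <- list(random_point(cfg$maze_radius - 10))
    total <- 0
    # enough waypoints to fill dur_s at the nominal speed
    while (total < dur_s * cfg$run_speed * 1.2) {
      p <- random_point(cfg$maze_radius - 10)
      total <- total + sqrt(sum((p - pts[[length(pts)]])^2))
      pts[[length(pts) + 1]] <- p
    }
    path <- traverse(do.call(rbind, pts), cfg$run_speed * 0.8, fs)
    path[seq_len(min(nrow(path), round(dur_s * fs))), , drop = FALSE]
  }

  segs$pre <- forage(cfg$pre_probe_s)
  n_pre <- nrow(segs$pre)
  cursor <- n_pre  # frames so far
  learn_segs <- list()
  for (ti in seq_len(cfg$n_trials)) {
    gap <- dwell_at(box_center, cfg$inter_trial_s, fs, jitter = 2)
    wp <- trial_waypoints(cfg, lens[ti])
    g <- cfg$goals_current
    gi1 <- which(wp[, 1] == g[1, 1] & wp[, 2] == g[1, 2])[1]
    gi2 <- which(wp[, 1] == g[2, 1] & wp[, 2] == g[2, 2])[1]
    p1 <- traverse(wp[1:gi1, , drop = FALSE], cfg$run_speed, fs)
    d1 <- dwell_at(g[1, ], cfg$dwell_s, fs)
    p2 <- traverse(wp[gi1:gi2, , drop = FALSE], cfg$run_speed, fs)
    d2 <- dwell_at(g[2, ], cfg$dwell_s, fs)
    p3 <- traverse(wp[gi2:nrow(wp), , drop = FALSE], cfg$run_speed, fs)
    trial_path <- rbind(p1, d1, p2, d2, p3)
    start_f <- cursor + nrow(gap) + 1
    end_f <- cursor + nrow(gap) + nrow(trial_path)
    trial_rows <- rbind(trial_rows,
                        data.frame(start_s = (start_f - 1) / fs,
                                   end_s = (end_f - 1) / fs))
    learn_segs[[ti]] <- rbind(gap, trial_path)
    cursor <- end_f
  }
  segs$learn <- do.call(rbind, learn_segs)
  segs$post <- forage(cfg$post_probe_s)
  xy <- rbind(segs$pre, segs$learn, segs$post)
  n <- nrow(xy)
  track <- gs_track((0:(n - 1)) / fs, xy[, 1], xy[, 2])
  post_start <- (n_pre + nrow(segs$learn)) / fs
  list(track = track, trials = trial_rows,
       probes = list(pre = c(0, (n_pre - 1) / fs),
                     post = c(post_start, (n - 1) / fs)))
}

smooth_noise <- function(n, scale_samples) {
  # low-pass white noise by moving average (cumsum form), unit sd
  k <- scale_samples
  z <- rnorm(n + k)
  cs <- c(0, cumsum(z))
  f <- (cs[seq_len(n) + k] - cs[seq_len(n)]) / k
  f / sd(f)
}

#' Generate per-region LFP signals
#'
#' dCA1: theta oscillation plus noise and (optionally) ripple-band bursts
#' at immobile at-goal times. mOFC: phase-lagged theta (lag jitter sets the
#' attainable PLV) plus low and high gamma whose envelopes are modulated by
#' the dCA1 theta phase with depth `pac_depth`.
#'
#' @param cfg A [synth_config()].
#' @param track The 50-Hz track (for speed/goal gating of ripple bursts).
#' @return List with `lfp` (named list of [gs_lfp()]), `theta_phase`
#'   (ground-truth phase), `swr_times` (burst centers, s).
#' @export
generate_lfp <- function(cfg, track) {
  set.seed(cfg$seed + 1L)
  fs <- LFP_FS
  dur <- track$times[length(track$times)]
  n <- ceiling(dur * fs) + 1
  t <- (0:(n - 1)) / fs
  # theta phase with slow drift so the rhythm is not a perfect sinusoid
  drift <- 0.3 * smooth_noise(n, fs)  # radians
  phase <- 2 * pi * cfg$theta_hz * t + drift
  theta <- cos(phase)
  ca1 <- cfg$theta_amp * theta + rnorm(n, sd = cfg$noise_sd)

  # ripple bursts at immobile at-goal samples
  sp_fun <- speed_interpolator(track)
  at_goal <- rep(FALSE, n)
  xi <- approx(track$times, track$x, xout = t, rule = 2)$y
  yi <- approx(track$times, track$y, xout = t, rule = 2)$y
  for (g in seq_len(2)) {
    d <- sqrt((xi - cfg$goals_current[g, 1])^2 +
                (yi - cfg$goals_current[g, 2])^2)
    at_goal <- at_goal | d <= 15
  }
  eligible <- which(at_goal & sp_fun(t) < 4)
  swr_times <- numeric(0)
  if (length(eligible) && cfg$swr_rate_goal > 0) {
    n_ev <- rpois(1, cfg$swr_rate_goal * length(eligible) / fs)
    if (n_ev > 0) {
      centers <- sort(sample(eligible, min(n_ev, length(eligible))))
      swr_times <- t[centers]
      burst_t <- seq(-0.04, 0.04, by = 1 / fs)
      burst <- 6 * cfg$noise_sd * exp(-burst_t^2 / (2 * 0.012^2)) *
        cos(2 * pi * 180 * burst_t)
      for (c0 in centers) {
        idx <- c0 + seq_along(burst_t) - ceiling(length(burst_t) / 2)
        ok <- idx >= 1 & idx <= n
        ca1[idx[ok]] <- ca1[idx[ok]] + burst[ok]
      }
    }
  }

  lag_noise <- if (cfg$plv_lag_jitter > 0)
    cfg$plv_lag_jitter * smooth_noise(n, round(fs / 4)) else numeric(n)
  mofc_theta <- cos(phase + cfg$plv_lag + lag_noise)
  env <- function(depth) 1 + depth * cos(phase - cfg$pac_phase)
  gpsi1 <- 2 * pi * cfg$gamma_hz[["low"]] * t + 0.5 * smooth_noise(n, fs)
  gpsi2 <- 2 * pi * cfg$gamma_hz[["high"]] * t + 0.5 * smooth_noise(n, fs)
  mofc <- 0.8 * cfg$theta_amp * mofc_theta +
    cfg$gamma_amp * env(cfg$pac_depth) * cos(gpsi1) +
    0.6 * cfg$gamma_amp * env(cfg$pac_depth) * cos(gpsi2) +
    rnorm(n, sd = cfg$noise_sd)

  list(lfp = list(dCA1 = gs_lfp(ca1, "dCA1"), mOFC = gs_lfp(mofc, "mOFC")),
       theta_phase = (phase + pi) %% (2 * pi) - pi,
       swr_times = swr_times)
}

vm_factor <- function(phase, kappa, mu = 0) {
  exp(kappa * cos(phase - mu)) / besselI(kappa, 0)
}

#' Generate unit spike trains with known ground truth
#'
#' Place cells fire as inhomogeneous Poisson processes with Gaussian
#' spatial tuning (thinning at 1-kHz resolution); goal cells have fields at
#' the previous-day goals before learning and, when their remap flag is
#' set, at the current-day goals from learning onward; interneurons fire at
#' a high quasi-uniform rate. A configurable fraction of units is
#' theta-locked via a von Mises rate multiplier. Planted short-latency
#' pairs insert target spikes at a fixed latency after reference spikes
#' with the stated excess probability; planted assembly members co-spike
#' within 20 ms of latent events.
#'
#' @param cfg A [synth_config()].
#' @param track The 50-Hz track.
#' @param lfp_info Result of [generate_lfp()] (for the theta phase).
#' @param learning_window `c(start_s, end_s)` of the learning session.
#' @return List with `units` (list of [gs_unit()]) and `truth` (data frame
#'   of per-unit ground-truth tuning plus pair/assembly bookkeeping).
#' @export
generate_spikes <- function(cfg, track, lfp_info, learning_window) {
  set.seed(cfg$seed + 2L)
  fs <- LFP_FS
  dur <- track$times[length(track$times)]
  n <- ceiling(dur * fs) + 1
  t <- (0:(n - 1)) / fs
  xi <- approx(track$times, track$x, xout = t, rule = 2)$y
  yi <- approx(track$times, track$y, xout = t, rule = 2)$y
  phase <- lfp_info$theta_phase
  if (length(phase) != n) phase <- rep_len(phase, n)

  specs <- list(); truth <- NULL
  add_spec <- function(region, kind, center_pre, center_post, remap) {
    id <- sprintf("%s_%s_%02d", region, kind, length(specs) + 1)
    locked <- runif(1) < cfg$theta_locked_fraction
    mu <- runif(1, -pi, pi)
    specs[[length(specs) + 1]] <<- list(
      id = id, region = region, kind = kind,
      center_pre = center_pre, center_post = center_post, remap = remap,
      locked = locked, mu = mu)
    truth <<- rbind(truth, data.frame(
      unit_id = id, region = region, kind = kind,
      center_pre_x = center_pre[1], center_pre_y = center_pre[2],
      center_post_x = center_post[1], center_post_y = center_post[2],
      remap = remap, theta_locked = locked, stringsAsFactors = FALSE))
  }
  for (rg in c("dCA1", "mOFC")) {
    for (i in seq_len(cfg$n_place[[rg]])) {
      ctr <- random_point(cfg$maze_radius - 20)
      add_spec(rg, "place", ctr, ctr, FALSE)
    }
    for (i in seq_len(cfg$n_goal[[rg]])) {
      remap <- runif(1) < cfg$goal_remap_fraction
      gp <- cfg$goals_previous[1 + (i %% 2), ]
      gc <- cfg$goals_current[1 + (i %% 2), ]
      if (remap) add_spec(rg, "goal", gp, gc, TRUE)
      else add_spec(rg, "goal", gc, gc, FALSE)
    }
    for (i in seq_len(cfg$n_interneuron[[rg]]))
      add_spec(rg, "interneuron", c(NA, NA), c(NA, NA), FALSE)
  }

  pre_mask <- t < learning_window[1]
  units <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (s$kind == "interneuron") {
      rate <- rep(cfg$interneuron_rate, n)
    } else {
      ctr_x <- ifelse(pre_mask, s$center_pre[1], s$center_post[1])
      ctr_y <- ifelse(pre_mask, s$center_pre[2], s$center_post[2])
      d2 <- (xi - ctr_x)^2 + (yi - ctr_y)^2
      rate <- cfg$baseline_rate +
        cfg$place_peak * exp(-d2 / (2 * cfg$place_sigma^2))
    }
    if (s$locked) rate <- rate * vm_factor(phase, cfg$theta_kappa, s$mu)
    st <- t[runif(n) < rate / fs]
    metrics <- if (s$kind == "interneuron") c(0.30, 4) else c(0.60, 3)
    units[[k]] <- gs_unit(s$id, s$region, st, metrics[1], metrics[2], dur)
  }
  names(units) <- vapply(specs, `[[`, "", "id")

  # planted short-latency pairs: excess target spikes at fixed latency
  if (!is.null(cfg$ccg_pairs) && nrow(cfg$ccg_pairs)) {
    for (i in seq_len(nrow(cfg$ccg_pairs))) {
      pr <- cfg$ccg_pairs[i, ]
      ref <- units[[pr$ref]]$spike_times
      extra <- ref[runif(length(ref)) < pr$excess_p] + pr$latency_ms / 1000
      tgt <- sort(unique(c(units[[pr$target]]$spike_times, extra)))
      u <- units[[pr$target]]
      units[[pr$target]] <- gs_unit(u$unit_id, u$region, tgt,
                                    u$trough_to_peak, u$acg_tau_rise, dur)
    }
  }

  # planted assemblies: members co-spike around latent events
  assembly_events <- list()
  if (!is.null(cfg$assemblies) && length(cfg$assemblies)) {
    win <- learning_window
    for (ai in seq_along(cfg$assemblies)) {
      members <- cfg$assemblies[[ai]]
      n_ev <- rpois(1, cfg$assembly_rate * diff(win))
      ev <- sort(runif(n_ev, win[1], win[2]))
      assembly_events[[ai]] <- ev
      for (m in members) {
        extra <- rep(ev, each = 2) + runif(2 * length(ev), -0.009, 0.009)
        u <- units[[m]]
        st <- sort(unique(c(u$spike_times, extra)))
        units[[m]] <- gs_unit(u$unit_id, u$region, st, u$trough_to_peak,
                              u$acg_tau_rise, dur)
      }
    }
  }

  list(units = units, truth = truth, assembly_events = assembly_events)
}

#' Generate a complete synthetic session
#'
#' Runs [generate_trajectory()], [generate_lfp()] and [generate_spikes()]
#' under one master seed and assembles a validated [gs_session()]. Ground
#' truth (unit tuning, planted pairs and assemblies, ripple-burst times,
#' the path-length schedule) is attached as the `"ground_truth"`
#' attribute.
#'
#' @param cfg A [synth_config()].
#' @return A `gs_session`.
#' @export
generate_session <- function(cfg = synth_config()) {
  traj <- generate_trajectory(cfg)
  lfp_info <- generate_lfp(cfg, traj$track)
  lw <- c(traj$probes$pre[2], traj$probes$post[1])
  spk <- generate_spikes(cfg, traj$track, lfp_info, lw)
  s <- gs_session(sprintf("synth_seed%d", cfg$seed), spk$units, traj$track,
                  lfp_info$lfp, cfg$goals_current, cfg$goals_previous,
                  traj$trials, traj$probes, cfg$start_box, cfg$maze_radius)
  attr(s, "ground_truth") <- list(
    units = spk$truth, swr_times = lfp_info$swr_times,
    theta_phase = lfp_info$theta_phase,
    assembly_events = spk$assembly_events,
    path_schedule = path_length_schedule(cfg), config = cfg)
  validate_session(s)
  s
}
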