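#' Instantaneous running speed from a 50-Hz track
#'
#' Centered finite-difference speed smoothed with a 5-sample moving
#' average. Endpoints use one-sided differences. Speeds are magnitudes and
#' therefore non-negative by construction.
#'
#' @param track A [gs_track()].
#' @return Numeric vector of speeds in cm/s, same length as the track.
#' @export
compute_velocity <- function(track) {
  n <- length(track$times)
  if (n < 3) stop("need at least 3 track samples to estimate velocity")
  x <- track$x; y <- track$y; t <- track$times
  vx <- numeric(n); vy <- numeric(n)
  idx <- 2:(n - 1)
  vx[idx] <- (x[idx + 1] - x[idx - 1]) / (t[idx + 1] - t[idx - 1])
  vy[idx] <- (y[idx + 1] - y[idx - 1]) / (t[idx + 1] - t[idx - 1])
  vx[1] <- (x[2] - x[1]) / (t[2] - t[1]); vy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  vx[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  sp <- sqrt(vx^2 + vy^2)
  # 5-sample moving average, shrinking at the edges
  k <- 5
  csum <- cumsum(c(0, sp))
  lo <- pmax(seq_len(n) - 2, 1); hi <- pmin(seq_len(n) + 2, n)
  (csum[hi + 1] - csum[lo]) / (hi - lo + 1)
}

in_roi <- function(track, goal, radius) {
  sqrt((track$x - goal[1])^2 + (track$y - goal[2])^2) <= radius
}

merge_frame_runs <- function(inside, merge_gap) {
  # runs of TRUE frames; adjacent runs merged when the gap <= merge_gap
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) == 0) return(seg)
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    gap <- seg[i, 1] - merged[nrow(merged), 2] - 1
    if (gap <= merge_gap) merged[nrow(merged), 2] <- seg[i, 2]
    else merged <- rbind(merged, seg[i, ])
  }
  merged
}

#' Detect goal-site visits in a probe or session track
#'
#' A visit is a run of consecutive frames inside the 15-cm circular ROI
#' around a goal; two adjacent in-ROI runs are merged into one visit when
#' the gap between them does not exceed `merge_gap` frames (about 1 s at
#' 50 Hz).
#'
#' @param track A [gs_track()] (or a windowed subset of one).
#' @param goals 2-column matrix of goal coordinates (one row per goal).
#' @param radius ROI radius, cm.
#' @param merge_gap Maximum between-run gap, in frames, for merging.
#' @return Data frame with `goal`, `start_frame`, `end_frame`,
#'   `start_s`, `end_s`; zero rows when the track never enters an ROI.
#' @export
detect_goal_visits <- function(track, goals, radius = 15, merge_gap = 50) {
  stopifnot(radius > 0)
  goals <- as_goal_matrix_any(goals)
  out <- NULL
  for (g in seq_len(nrow(goals))) {
    seg <- merge_frame_runs(in_roi(track, goals[g, ], radius), merge_gap)
    if (nrow(seg))
      out <- rbind(out, data.frame(goal = g, start_frame = seg[, 1],
                                   end_frame = seg[, 2],
                                   start_s = track$times[seg[, 1]],
                                   end_s = track$times[seg[, 2]]))
  }
  if (is.null(out))
    out <- data.frame(goal = integer(0), start_frame = integer(0),
                      end_frame = integer(0), start_s = numeric(0),
                      end_s = numeric(0))
  out[order(out$start_frame), , drop = FALSE]
}

as_goal_matrix_any <- function(g) {
  if (is.matrix(g)) g else matrix(as.numeric(g), ncol = 2, byrow = TRUE)
}

window_track <- function(track, start_s, end_s) {
  keep <- track$times >= start_s & track$times <= end_s
  tr <- structure(list(times = track$times[keep], x = track$x[keep],
                       y = track$y[keep], fs = track$fs,
                       velocity = track$velocity[keep]), class = "gs_track")
  attr(tr, "frame_offset") <- which(keep)[1] - 1
  tr
}

#' Segment learning trials into Goal and Navigation epochs
#'
#' Each complete trial is split into four contiguous epochs ordered by the
#' first-reached goal (not by goal identity): `Navigation1` from start-box
#' exit to the first entry of the first-reached goal's 15-cm zone, `Goal1`
#' the dwell there, `Navigation2` from leaving the first zone to entering
#' the second, and `Goal2` the dwell at the second goal. A Goal dwell ends
#' at the last in-zone frame before a continuous absence of at least 1 s.
#' Trials that never reach both goals are flagged incomplete and excluded
#' with a warning.
#'
#' @param track A [gs_track()].
#' @param goals 2x2 matrix of current-day goal coordinates.
#' @param trials Data frame with `start_s`, `end_s`.
#' @param start_box Rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param radius Goal-zone radius, cm.
#' @return Data frame with `label`, `trial`, `block`, `start_s`, `end_s`;
#'   block index is `ceiling(trial / 10)`.
#' @export
segment_epochs <- function(track, goals, trials,
                           start_box = c(-80, -60, -15, 15), radius = 15) {
  goals <- as_goal_matrix_any(goals)
  out <- NULL; incomplete <- integer(0)
  fs <- track$fs
  for (ti in seq_len(nrow(trials))) {
    tr <- window_track(track, trials$start_s[ti], trials$end_s[ti])
    n <- length(tr$times)
    if (n < 3) { incomplete <- c(incomplete, ti); next }
    outside_box <- !(tr$x >= start_box[1] & tr$x <= start_box[2] &
                     tr$y >= start_box[3] & tr$y <= start_box[4])
    exit_f <- which(outside_box)[1]
    if (is.na(exit_f)) { incomplete <- c(incomplete, ti); next }
    in1 <- in_roi(tr, goals[1, ], radius)
    in2 <- in_roi(tr, goals[2, ], radius)
    e1 <- which(in1 & seq_len(n) >= exit_f)[1]
    e2 <- which(in2 & seq_len(n) >= exit_f)[1]
    if (is.na(e1) && is.na(e2)) { incomplete <- c(incomplete, ti); next }
    first_goal <- if (is.na(e2) || (!is.na(e1) && e1 <= e2)) 1L else 2L
    ins <- list(in1, in2)
    entry1 <- min(e1, e2, na.rm = TRUE)
    dep1 <- dwell_end(ins[[first_goal]], entry1, fs)
    second_goal <- 3L - first_goal
    entry2 <- which(ins[[second_goal]] & seq_len(n) > dep1)[1]
    if (is.na(entry2)) { incomplete <- c(incomplete, ti); next }
    dep2 <- dwell_end(ins[[second_goal]], entry2, fs)
    bounds <- c(exit_f, entry1, dep1 + 1L, entry2, dep2 + 1L)
    labels <- c("Navigation1", "Goal1", "Navigation2", "Goal2")
    out <- rbind(out, data.frame(
      label = labels, trial = ti, block = ceiling(ti / 10),
      start_s = tr$times[bounds[1:4]],
      end_s = tr$times[pmin(bounds[2:5], n)]
    ))
  }
  if (length(incomplete))
    warning(sprintf("excluded %d incomplete trial(s): %s",
                    length(incomplete), paste(incomplete, collapse = ", ")))
  if (is.null(out))
    out <- data.frame(label = character(0), trial = integer(0),
                      block = integer(0), start_s = numeric(0),
                      end_s = numeric(0))
  out
}

# last in-zone frame of the dwell starting at `entry`: the dwell ends at the
# last inside frame before a continuous absence of >= 1 s
dwell_end <- function(inside, entry, fs) {
  n <- length(inside)
  gap_limit <- fs  # 1 s of frames
  last_in <- entry
  i <- entry
  while (i < n) {
    i <- i + 1
    if (inside[i]) last_in <- i
    else if (i - last_in >= gap_limit) break
  }
  last_in
}

#' Path length of one trial
#'
#' Sum of successive Euclidean step lengths over the trial window.
#'
#' @param track A [gs_track()].
#' @param trial A list or one-row data frame with `start_s` and `end_s`.
#' @return Path length in cm.
#' @export
trajectory_length <- function(track, trial) {
  tr <- window_track(track, trial$start_s, trial$end_s)
  if (length(tr$times) < 2) return(0)
  sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
}

#' Fit a continuous one-breakpoint piecewise-linear model
#'
#' Fits `y = b0 + b1 * x + b2 * max(0, x - tau)` by ordinary least squares
#' at every candidate integer breakpoint `tau` on a grid excluding endpoint
#' trials (so both sides of the break are supported), and returns the
#' minimum-RSS fit. Ties are broken toward the smallest `tau`.
#'
#' @param y Per-trial values (e.g., trajectory length), trial order.
#' @param x Trial numbers (default `1:length(y)`).
#' @return A `gs_breakpoint` list: `tau`, `beta0`, `beta1`, `beta2`, `rss`,
#'   `pre_slope` (= beta1), `post_slope` (= beta1 + beta2).
#' @export
fit_breakpoint <- function(y, x = seq_along(y)) {
  stopifnot(length(y) >= 5, all(is.finite(y)))
  candidates <- seq(min(x) + 2, max(x) - 2)
  best <- NULL
  for (tau in candidates) {
    h <- pmax(0, x - tau)
    X <- cbind(1, x, h)
    if (qr(X)$rank < 3) next
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      b <- fit$coefficients
      best <- list(tau = tau, beta0 = b[[1]], beta1 = b[[2]],
                   beta2 = b[[3]], rss = rss,
                   pre_slope = b[[2]], post_slope = b[[2]] + b[[3]])
    }
  }
  if (is.null(best)) stop("no admissible breakpoint candidate")
  structure(best, class = "gs_breakpoint")
}

#' Z-scored distribution of navigation running speeds
#'
#' Bins speeds into 2 cm/s intervals over 0-50 cm/s (25 bins) and z-scores
#' the bin counts across bins.
#'
#' @param speeds Numeric vector of speeds, cm/s.
#' @param breaks Bin edges (default `seq(0, 50, by = 2)`).
#' @return Numeric vector of 25 z-scored counts (mean 0, sd 1).
#' @export
velocity_distribution <- function(speeds, breaks = seq(0, 50, by = 2)) {
  counts <- as.numeric(table(cut(pmin(speeds, max(breaks) - 1e-9),
                                 breaks = breaks, include.lowest = TRUE)))
  if (sd(counts) == 0 || sum(counts > 0) < 2)
    stop("speed histogram has (near-)zero variance across bins")
  (counts - mean(counts)) / sd(counts)
}
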