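#' Occupancy-normalized firing-rate map
#'
#' Position samples and spikes (restricted to periods with running speed
#' above `speed_min`) are binned on a square 5-cm grid covering the arena.
#' Rates are spike counts divided by occupancy per bin; bins occupied for
#' less than 0.2 s are masked. The rate map is then smoothed with a 5-bin
#' Gaussian kernel (sigma = 1.5 bins) that is renormalized over valid bins
#' so that masked (unvisited) bins neither receive nor donate rate.
#'
#' Grid convention: bin (1,1) sits at the lower-left corner of the square
#' `[-extent, extent]^2`; positions are assigned to bins by floor division.
#'
#' @param unit A [gs_unit()] (or any list with `spike_times`).
#' @param track A [gs_track()]; restrict to a probe window beforehand with
#'   the `window` argument if needed.
#' @param speed_min Minimum speed in cm/s (strictly greater than).
#' @param bin_cm Bin side, cm.
#' @param extent Half-width of the square grid, cm (default covers the
#'   150-cm board).
#' @param window Optional `c(start_s, end_s)` restriction.
#' @param smooth Smooth the rate map (default `TRUE`).
#' @return A `gs_ratemap`: `rate` (matrix, Hz; `NA` where masked),
#'   `occupancy` (s), `valid` (logical matrix), `peak_rate`, `peak_bin`,
#'   `bin_cm`, `origin` (grid lower-left corner in cm).
#' @export
compute_rate_map <- function(unit, track, speed_min = 4, bin_cm = 5,
                             extent = 75, window = NULL, smooth = TRUE) {
  tr <- track
  if (!is.null(window)) tr <- window_track(track, window[1], window[2])
  keep <- tr$velocity > speed_min
  if (!any(keep)) stop("no track samples above the speed threshold")
  nb <- ceiling(2 * extent / bin_cm)
  origin <- c(-extent, -extent)
  bx <- bin_index(tr$x[keep], origin[1], bin_cm, nb)
  by <- bin_index(tr$y[keep], origin[2], bin_cm, nb)
  occ <- matrix(0, nb, nb)
  tab <- table(factor(bx, levels = 1:nb), factor(by, levels = 1:nb))
  occ <- occ + as.numeric(tab) * (1 / tr$fs)
  dim(occ) <- c(nb, nb)
  if (sum(occ) == 0) stop("zero total occupancy")
  # spikes: assign each spike the position of the nearest track sample,
  # keep it only when that sample passes the speed gate
  spk <- matrix(0, nb, nb)
  st <- unit$spike_times
  st <- st[st >= tr$times[1] & st <= tr$times[length(tr$times)]]
  if (length(st)) {
    si <- round((st - tr$times[1]) * tr$fs) + 1
    si <- pmin(pmax(si, 1), length(tr$times))
    ok <- keep[si]
    if (any(ok)) {
      sx <- bin_index(tr$x[si[ok]], origin[1], bin_cm, nb)
      sy <- bin_index(tr$y[si[ok]], origin[2], bin_cm, nb)
      tb <- table(factor(sx, levels = 1:nb), factor(sy, levels = 1:nb))
      spk <- matrix(as.numeric(tb), nb, nb)
    }
  }
  valid <- occ >= 0.2
  rate <- spk / occ
  rate[!valid] <- NA
  if (smooth) rate <- masked_gauss_smooth(rate, valid, size = 5, sigma = 1.5)
  pk <- if (any(valid)) max(rate[valid]) else 0
  pb <- if (any(valid)) which(rate == pk, arr.ind = TRUE)[1, ] else c(NA, NA)
  structure(list(rate = rate, occupancy = occ, valid = valid,
                 peak_rate = pk, peak_bin = unname(pb),
                 bin_cm = bin_cm, origin = origin),
            class = "gs_ratemap")
}

bin_index <- function(p, origin, bin_cm, nb) {
  pmin(pmax(floor((p - origin) / bin_cm) + 1, 1), nb)
}

# Gaussian smoothing over a masked grid: kernel weights renormalized over
# valid bins so masked bins are excluded from the average
masked_gauss_smooth <- function(rate, valid, size = 5, sigma = 1.5) {
  half <- (size - 1) / 2
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  ker <- outer(g1, g1)
  nb <- nrow(rate)
  out <- matrix(NA_real_, nb, nb)
  vals <- rate; vals[!valid] <- 0
  num <- conv2_same(vals, ker)
  den <- conv2_same(valid * 1, ker)
  out[valid] <- num[valid] / den[valid]
  out
}

conv2_same <- function(m, ker) {
  kh <- (nrow(ker) - 1) / 2
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (di in -kh:kh) for (dj in -kh:kh) {
    w <- ker[di + kh + 1, dj + kh + 1]
    si <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 - dj):min(n2, n2 - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * m[si, sj]
  }
  out
}

#' Skaggs spatial information of a rate map
#'
#' `I = sum_i p_i (r_i / rbar) log2(r_i / rbar)` in bits per spike, where
#' `p_i` is occupancy probability over valid bins, `r_i` the bin rate and
#' `rbar = sum_i p_i r_i` the occupancy-weighted mean rate. Zero-rate bins
#' contribute 0 (the `0 log 0` convention).
#'
#' @param map A `gs_ratemap`.
#' @return Bits per spike; `NA` with a `"zero_mean_rate"` attribute when the
#'   mean rate is 0.
#' @export
spatial_information <- function(map) {
  v <- map$valid
  if (!any(v)) stop("rate map has no valid bins")
  p <- map$occupancy[v] / sum(map$occupancy[v])
  r <- map$rate[v]
  rbar <- sum(p * r)
  if (rbar == 0) return(structure(NA_real_, reason = "zero_mean_rate"))
  ratio <- r / rbar
  terms <- ifelse(r > 0, p * ratio * log2(ratio), 0)
  sum(terms)
}

#' High-firing peak region of a rate map
#'
#' All valid bins whose rate is at least `frac` of the map's peak rate.
#' Units with peak rate of 1 Hz or less are excluded from downstream
#' goal-overlap classification.
#'
#' @param map A `gs_ratemap`.
#' @param frac Fraction of the peak rate (default 0.8).
#' @param min_peak Peak-rate inclusion threshold, Hz (strictly greater
#'   than).
#' @return Integer matrix of `(row, col)` bins; attribute `size` gives the
#'   bin count (the field-size control). `NULL` when the unit is excluded.
#' @export
peak_region <- function(map, frac = 0.8, min_peak = 1) {
  if (map$peak_rate <= min_peak) return(NULL)
  sel <- which(map$valid & !is.na(map$rate) &
                 map$rate >= frac * map$peak_rate, arr.ind = TRUE)
  structure(sel, size = nrow(sel))
}

goal_bin <- function(goal_xy, map) {
  nb <- nrow(map$rate)
  c(bin_index(goal_xy[1], map$origin[1], map$bin_cm, nb),
    bin_index(goal_xy[2], map$origin[2], map$bin_cm, nb))
}

#' Overlap between a peak region and the goal window of one goal
#'
#' The goal window is the 3x3 square of bins centered on the bin containing
#' the goal (a 15-cm neighborhood at 5-cm bins); the overlap score is the
#' number of peak-region bins inside that window, between 0 and 9.
#'
#' @param peak_bins Bin matrix from [peak_region()].
#' @param goal_xy Goal coordinates `(x, y)`, cm.
#' @param map The `gs_ratemap` providing the grid geometry.
#' @return Integer overlap count.
#' @export
goal_overlap <- function(peak_bins, goal_xy, map) {
  nb <- nrow(map$rate)
  if (any(abs(goal_xy) > nb * map$bin_cm / 2))
    stop("goal lies outside the rate-map grid")
  gb <- goal_bin(goal_xy, map)
  if (is.null(peak_bins) || nrow(peak_bins) == 0) return(0L)
  inside <- abs(peak_bins[, 1] - gb[1]) <= 1 & abs(peak_bins[, 2] - gb[2]) <= 1
  sum(inside)
}

set_overlap <- function(peak_bins, goals, map) {
  max(goal_overlap(peak_bins, goals[1, ], map),
      goal_overlap(peak_bins, goals[2, ], map))
}

peak_to_goal_distance <- function(map, goals) {
  if (any(is.na(map$peak_bin))) return(NA_real_)
  ctr <- map$origin + (map$peak_bin - 0.5) * map$bin_cm
  min(sqrt(rowSums(sweep(goals, 2, ctr)^2)))
}

#' Classify a unit's goal relation and reorganization status
#'
#' A unit is goal-related when its 80%-peak region overlaps the
#' previous-day goal set in the pre-probe map or the current-day goal set
#' in the post-probe map. Among goal-related units, reorganization units
#' overlap the previous-day set pre-probe AND the current-day set
#' post-probe; the rest are non-reorganization. Per goal set, the overlap
#' score is the larger of the two per-goal overlaps. Units failing the
#' 1-Hz peak-rate rule in either map are excluded.
#'
#' @param pre_map,post_map `gs_ratemap`s from the pre- and post-probe.
#' @param goals_prev,goals_curr 2x2 goal matrices.
#' @return A `gs_goal_class` list with overlap scores, peak-to-goal
#'   distances, `goal_related`, `reorganization`, and `excluded` (with
#'   `reason`) flags.
#' @export
classify_goal_cells <- function(pre_map, post_map, goals_prev, goals_curr) {
  goals_prev <- as_goal_matrix_any(goals_prev)
  goals_curr <- as_goal_matrix_any(goals_curr)
  pr <- peak_region(pre_map); po <- peak_region(post_map)
  if (is.null(pr) || is.null(po)) {
    return(structure(list(excluded = TRUE, reason = "peak rate <= 1 Hz",
                          goal_related = NA, reorganization = NA),
                     class = "gs_goal_class"))
  }
  ov_prev_pre <- set_overlap(pr, goals_prev, pre_map)
  ov_curr_post <- set_overlap(po, goals_curr, post_map)
  goal_related <- ov_prev_pre > 0 || ov_curr_post > 0
  reorganization <- ov_prev_pre > 0 && ov_curr_post > 0
  structure(list(
    excluded = FALSE,
    overlap_prev = ov_prev_pre, overlap_curr = ov_curr_post,
    peak_to_goal_prev = peak_to_goal_distance(pre_map, goals_prev),
    peak_to_goal_curr = peak_to_goal_distance(post_map, goals_curr),
    field_size_pre = attr(pr, "size"), field_size_post = attr(po, "size"),
    goal_related = goal_related,
    reorganization = reorganization,
    non_reorganization = goal_related && !reorganization
  ), class = "gs_goal_class")
}

#' Per-session labeled fractions within region and cell-type strata
#'
#' Fractions of labeled cells are computed within each session x region x
#' cell-type stratum (labeled / eligible); empty strata are excluded.
#'
#' @param labels Data frame with columns `session_id`, `region`,
#'   `cell_type` and a logical `labeled` column (e.g., goal-related or
#'   reorganization).
#' @return Data frame with one row per non-empty stratum and its
#'   `fraction`.
#' @export
session_fractions <- function(labels) {
  stopifnot(all(c("session_id", "region", "cell_type", "labeled") %in%
                  names(labels)))
  agg <- aggregate(labeled ~ session_id + region + cell_type, data = labels,
                   FUN = function(z) c(n = length(z), frac = mean(z)))
  out <- data.frame(agg[, 1:3],
                    n_eligible = agg$labeled[, "n"],
                    fraction = agg$labeled[, "frac"])
  out[out$n_eligible > 0, , drop = FALSE]
}
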