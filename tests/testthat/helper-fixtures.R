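# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A compact synthetic session reused across suites: short probes, fast
# trials, a planted short-latency pair and a planted assembly.
fix_session <- function() {
  if (is.null(.fixture_cache$session)) {
    cfg <- synth_config(
      seed = 5, pre_probe_s = 120, post_probe_s = 120,
      path_floor = 300, path_pre_slope = -40, run_speed = 25,
      ccg_pairs = data.frame(ref = 1, target = 2, latency_ms = 2,
                             excess_p = 0.3),
      assemblies = list(c(1, 3, 5, 7))
    )
    .fixture_cache$session <- generate_session(cfg)
  }
  .fixture_cache$session
}

# straight-line track moving at `speed` cm/s along x for `dur_s` seconds
straight_track <- function(speed = 20, dur_s = 10, y = 0) {
  n <- round(dur_s * 50)
  t <- (0:(n - 1)) / 50
  gs_track(t, -60 + speed * t, rep(y, n))
}

# stationary track at a point
still_track <- function(dur_s = 10, at = c(0, 0)) {
  n <- round(dur_s * 50)
  gs_track((0:(n - 1)) / 50, rep(at[1], n), rep(at[2], n))
}

# serpentine sweep of the square [-extent, extent]^2 at constant speed:
# near-uniform occupancy with every sample above the 4-cm/s speed gate
serpentine_track <- function(speed = 20, extent = 70, row_step = 5,
                             n_sweeps = 1) {
  ys <- seq(-extent, extent, by = row_step)
  wp <- do.call(rbind, lapply(seq_along(ys), function(i) {
    xs <- if (i %% 2 == 1) c(-extent, extent) else c(extent, -extent)
    cbind(xs, ys[i])
  }))
  wp <- do.call(rbind, replicate(n_sweeps, wp, simplify = FALSE))
  seg <- diff(wp)
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  n <- round(total / speed * 50)
  d <- seq(0, total, length.out = n)
  cum <- c(0, cumsum(lens))
  si <- pmin(findInterval(d, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (d - cum[si]) / pmax(lens[si], 1e-9)
  pos <- wp[si, , drop = FALSE] + seg[si, , drop = FALSE] * frac
  gs_track((0:(n - 1)) / 50, pos[, 1], pos[, 2])
}

# hand-built rate map with a single Gaussian field; grid matches
# compute_rate_map defaults (5-cm bins over [-75, 75])
toy_ratemap <- function(center, peak = 5, sigma_cm = 10, extent = 75,
                        bin_cm = 5) {
  nb <- ceiling(2 * extent / bin_cm)
  ctrs <- -extent + (seq_len(nb) - 0.5) * bin_cm
  rate <- outer(ctrs, ctrs, function(x, y)
    peak * exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * sigma_cm^2)))
  structure(list(rate = rate, occupancy = matrix(1, nb, nb),
                 valid = matrix(TRUE, nb, nb),
                 peak_rate = max(rate),
                 peak_bin = unname(which(rate == max(rate), arr.ind = TRUE)[1, ]),
                 bin_cm = bin_cm, origin = c(-extent, -extent)),
            class = "gs_ratemap")
}

# von Mises sampler (Best & Fisher rejection scheme)
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  (out + pi) %% (2 * pi) - pi
}

# homogeneous Poisson spike train on [0, dur]
rpoisson_train <- function(rate, dur) {
  n <- rpois(1, rate * dur)
  sort(runif(n, 0, dur))
}
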