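#' Standard frequency bands
#'
#' Theta 4-12 Hz, low gamma 30-60 Hz, high gamma 60-90 Hz, ripple
#' 150-250 Hz. The delta band used only for the theta/delta gate of theta-
#' cycle detection is 1-4 Hz (conventional choice).
#'
#' @param name Band name.
#' @return `c(lo, hi)` in Hz.
#' @export
band_spec <- function(name = c("theta", "low_gamma", "high_gamma",
                               "ripple", "delta")) {
  switch(match.arg(name),
         theta = c(4, 12), low_gamma = c(30, 60), high_gamma = c(60, 90),
         ripple = c(150, 250), delta = c(1, 4))
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward-backward
#' (zero net phase shift).
#'
#' @param x Numeric signal.
#' @param band `c(lo, hi)` Hz or a band name.
#' @param fs Sampling rate, Hz.
#' @return Filtered signal, same length.
#' @export
bandpass <- function(x, band, fs = LFP_FS) {
  if (is.character(band)) band <- band_spec(band)
  if (any(band >= fs / 2)) stop("band edges must be below Nyquist")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  out <- as.numeric(signal::filtfilt(bf, x))
  if (any(!is.finite(out)))
    stop(sprintf(paste("band %g-%g Hz is numerically unstable at fs = %g;",
                       "decimate the signal first"), band[1], band[2], fs))
  out
}

#' Analytic-signal phase and envelope
#'
#' Band-pass filters the signal and extracts the instantaneous phase and
#' amplitude envelope with the Hilbert (analytic-signal) transform. Phase
#' is the analytic-signal angle in `(-pi, pi]`: 0 at the filtered-signal
#' peak, +/-pi at troughs.
#'
#' @param x Numeric signal.
#' @param band `c(lo, hi)` Hz or a band name.
#' @param fs Sampling rate, Hz.
#' @return List with `phase`, `amplitude`, `filtered`, `band`.
#' @export
phase_series <- function(x, band, fs = LFP_FS) {
  filt <- bandpass(x, band, fs)
  a <- analytic_signal(filt)
  list(phase = Arg(a), amplitude = Mod(a), filtered = filt,
       band = if (is.character(band)) band_spec(band) else band)
}

# analytic signal via FFT: zero negative frequencies, double positive ones.
# The signal is zero-padded to a highly composite length (mixed-radix FFT
# degrades to quadratic cost near prime lengths) and truncated afterwards.
analytic_signal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  f <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  out <- fft(f * h, inverse = TRUE) / n
  out[seq_len(n0)]
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodograms with a 1-s window and 90% overlap,
#' yielding a 1-Hz frequency grid at 1 kHz sampling. Density scaling:
#' the PSD integrates to the signal variance (Parseval).
#'
#' @param x Numeric signal (at least 2 s long).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, s.
#' @param overlap Fractional overlap between windows.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_power <- function(x, fs = LFP_FS, window_s = 1, overlap = 0.9) {
  nw <- round(window_s * fs)
  if (length(x) < 2 * nw) stop("signal too short for Welch estimate")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  u <- sum(w^2)
  acc <- numeric(nw %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs * u)
    half <- p[1:(nw %/% 2 + 1)]
    # one-sided: double all but DC (and Nyquist when nw even)
    if (nw %% 2 == 0) half[2:(length(half) - 1)] <- 2 * half[2:(length(half) - 1)]
    else half[2:length(half)] <- 2 * half[2:length(half)]
    acc <- acc + half
  }
  list(freq = (0:(nw %/% 2)) * fs / nw, psd = acc / length(starts))
}

#' Mean band power from a Welch PSD
#'
#' @param psd Result of [welch_power()].
#' @param band `c(lo, hi)` Hz or a band name.
#' @return Mean PSD within the band (inclusive edges).
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) band <- band_spec(band)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  mean(psd$psd[sel])
}

#' Phase-locking value between two phase series
#'
#' `PLV = |mean(exp(i (phi1 - phi2)))|`: 1 for perfect synchronization
#' (constant phase offset), near 0 for independent phases.
#'
#' @param phase_a,phase_b Instantaneous phases in radians, equal length.
#' @param min_n Minimum number of samples.
#' @return Scalar in `[0, 1]`.
#' @export
plv <- function(phase_a, phase_b, min_n = 100) {
  if (length(phase_a) != length(phase_b)) stop("phase series length mismatch")
  if (length(phase_a) < min_n) stop("need at least ", min_n, " samples")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' n:m cross-frequency phase synchronization
#'
#' Coupling strength for n slow-rhythm cycles locking to m fast-rhythm
#' cycles: the slow phase is accelerated m-fold and the fast phase n-fold
#' so their difference is stationary exactly when the instantaneous
#' frequencies satisfy `m f_slow = n f_fast`, i.e.
#' `r_nm = |mean(exp(i (m phi_slow - n phi_fast)))|`. With theta at 8 Hz
#' and gamma at 40 Hz, the scan over 1:1 ... 1:10 peaks at 1:5.
#'
#' @param phase_slow,phase_fast Instantaneous phases in radians.
#' @param n,m Positive integer cycle counts (n slow : m fast).
#' @return Scalar in `[0, 1]`.
#' @export
nm_plv <- function(phase_slow, phase_fast, n, m) {
  if (n < 1 || m < 1 || n != round(n) || m != round(m))
    stop("n and m must be positive integers")
  if (length(phase_slow) != length(phase_fast))
    stop("phase series length mismatch")
  Mod(mean(exp(1i * (m * phase_slow - n * phase_fast))))
}

#' Normalized-entropy phase-amplitude modulation index
#'
#' The slow-band phase is divided into 18 bins of 20 degrees; the mean
#' fast-band amplitude per bin is normalized to a distribution `P_j`, whose
#' Shannon entropy `H` is compared with the uniform maximum
#' `Hmax = log(18)`: `MI = (Hmax - H) / Hmax`. MI is 0 when the amplitude
#' is uniform across phase bins and approaches 1 as the amplitude
#' concentrates in a single bin.
#'
#' @param phase Instantaneous phase of the slow band, radians.
#' @param amplitude Amplitude envelope of the fast band, same length.
#' @param n_bins Number of phase bins (18 bins of 20 degrees).
#' @return A `gs_mi` list: `mi`, `P` (bin distribution), `H`, `Hmax`,
#'   `bin_centers_deg`, `empty_bins` flag.
#' @export
pac_mi <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) stop("length mismatch")
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- findInterval(phase, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  means <- vapply(seq_len(n_bins), function(j) {
    a <- amplitude[idx == j]
    if (length(a)) mean(a) else 0
  }, numeric(1))
  empty <- any(tabulate(idx, n_bins) == 0)
  P <- means / sum(means)
  H <- -sum(ifelse(P > 0, P * log(P), 0))
  Hmax <- log(n_bins)
  structure(list(mi = (Hmax - H) / Hmax, P = P, H = H, Hmax = Hmax,
                 bin_centers_deg = (seq_len(n_bins) - 0.5) * 360 / n_bins,
                 empty_bins = empty),
            class = "gs_mi")
}

#' Phase-amplitude modulation index from two raw signals
#'
#' Convenience wrapper: filters `sig_phase` in the slow band and `sig_amp`
#' in the fast band, extracts phase and envelope, and calls [pac_mi()].
#'
#' @param sig_phase,sig_amp Raw signals (e.g., dCA1 and mOFC LFP).
#' @param band_phase,band_amp Band names or `c(lo, hi)` pairs.
#' @param fs Sampling rate, Hz.
#' @return A `gs_mi` list (see [pac_mi()]).
#' @export
pac_mi_signals <- function(sig_phase, sig_amp, band_phase = "theta",
                           band_amp = "low_gamma", fs = LFP_FS) {
  ph <- phase_series(sig_phase, band_phase, fs)
  am <- phase_series(sig_amp, band_amp, fs)
  pac_mi(ph$phase, am$amplitude)
}

#' Detect theta cycles
#'
#' Theta cycles are trough-to-trough intervals of the theta-filtered LFP
#' (troughs at analytic phase +/-pi) restricted to samples where running
#' speed exceeds 4 cm/s and the theta envelope exceeds three times the
#' delta envelope; samples inside the SWR exclusion mask are discarded.
#'
#' @param lfp A [gs_lfp()] (typically dCA1).
#' @param speed_fun Function mapping LFP sample times (s) to speed (cm/s).
#' @param swr_mask Optional logical vector (length of the LFP) of samples
#'   to exclude.
#' @param speed_min Speed gate, cm/s.
#' @param ratio_min Theta/delta envelope ratio gate.
#' @return Data frame of cycles with `start_s`, `end_s`.
#' @export
detect_theta_cycles <- function(lfp, speed_fun, swr_mask = NULL,
                                speed_min = 4, ratio_min = 3) {
  th <- phase_series(lfp$samples, "theta", lfp$fs)
  times <- (seq_along(lfp$samples) - 1) / lfp$fs
  # theta/delta envelope ratio evaluated on a 10x decimated signal (a
  # narrow 1-4 Hz band is numerically unstable at 1 kHz), then
  # interpolated back to the LFP grid
  ds <- 10
  xd <- as.numeric(signal::decimate(lfp$samples, ds))
  fsd <- lfp$fs / ds
  td <- (seq_along(xd) - 1) / fsd
  th_d <- phase_series(xd, "theta", fsd)$amplitude
  de_d <- phase_series(xd, "delta", fsd)$amplitude
  ratio_ok <- approx(td, th_d > ratio_min * de_d, xout = times,
                     method = "constant", rule = 2)$y > 0
  ok <- speed_fun(times) > speed_min & ratio_ok
  if (!is.null(swr_mask)) ok <- ok & !swr_mask
  # troughs: phase wraps from +pi to -pi
  ph <- th$phase
  wrap <- which(diff(ph) < -pi)
  if (length(wrap) < 2)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  starts <- wrap[-length(wrap)] + 1
  ends <- wrap[-1]
  keep <- vapply(seq_along(starts), function(i)
    all(ok[starts[i]:ends[i]]), logical(1))
  data.frame(start_s = times[starts[keep]], end_s = times[ends[keep]])
}

#' Detect sharp-wave ripples and build the exclusion mask
#'
#' Events are intervals where the z-scored ripple-band (150-250 Hz)
#' envelope exceeds 3 SD while running speed is below 4 cm/s; the baseline
#' mean/SD are computed over all below-threshold-speed samples of the
#' session. The exclusion mask covers every event plus the 100 ms that
#' follow it.
#'
#' @param lfp A [gs_lfp()] from dCA1.
#' @param speed_fun Function mapping LFP sample times (s) to speed (cm/s).
#' @param z_thresh Detection threshold in baseline SDs.
#' @param speed_max Immobility gate, cm/s.
#' @param pad_s Post-event mask extension, s.
#' @param min_duration_s Minimum above-threshold duration; brief chance
#'   crossings of the envelope are discarded.
#' @param merge_gap_s Crossings closer than this are merged into one
#'   event before the duration criterion.
#' @return List with `events` (data frame `start_s`, `end_s`) and `mask`
#'   (logical, one entry per LFP sample).
#' @export
detect_swr <- function(lfp, speed_fun, z_thresh = 3, speed_max = 4,
                       pad_s = 0.1, min_duration_s = 0.02,
                       merge_gap_s = 0.01) {
  env <- phase_series(lfp$samples, "ripple", lfp$fs)$amplitude
  times <- (seq_along(lfp$samples) - 1) / lfp$fs
  slow <- speed_fun(times) < speed_max
  mask <- logical(length(env))
  if (!any(slow))
    return(list(events = data.frame(start_s = numeric(0),
                                    end_s = numeric(0)), mask = mask))
  mu <- mean(env[slow]); sdv <- sd(env[slow])
  hit <- slow & (env - mu) / sdv > z_thresh
  seg <- merge_frame_runs(hit, round(merge_gap_s * lfp$fs))
  if (nrow(seg))
    seg <- seg[(seg[, 2] - seg[, 1] + 1) >= min_duration_s * lfp$fs, ,
               drop = FALSE]
  pad <- round(pad_s * lfp$fs)
  if (nrow(seg)) for (i in seq_len(nrow(seg)))
    mask[seg[i, 1]:min(length(mask), seg[i, 2] + pad)] <- TRUE
  events <- if (nrow(seg))
    data.frame(start_s = times[seg[, 1]], end_s = times[seg[, 2]])
  else data.frame(start_s = numeric(0), end_s = numeric(0))
  list(events = events, mask = mask)
}

#' Speed-power correlation in consecutive windows
#'
#' Band power and mean running speed are computed in consecutive
#' non-overlapping windows (200 ms by default) and correlated (Pearson).
#'
#' @param lfp A [gs_lfp()].
#' @param speed_fun Function mapping times (s) to speed (cm/s).
#' @param band Band name or `c(lo, hi)`.
#' @param window_s Window length, s.
#' @return List with `r` (Pearson correlation), `n_windows`, and the
#'   per-window `power` and `speed` vectors.
#' @export
speed_power_correlation <- function(lfp, speed_fun, band = "theta",
                                    window_s = 0.2) {
  nw <- round(window_s * lfp$fs)
  n_win <- length(lfp$samples) %/% nw
  if (n_win < 10) stop("need at least 10 windows")
  filt <- bandpass(lfp$samples, band, lfp$fs)
  times <- (seq_along(lfp$samples) - 1) / lfp$fs
  pw <- sp <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1) * nw + 1):(i * nw)
    pw[i] <- mean(filt[idx]^2)
    sp[i] <- mean(speed_fun(times[idx]))
  }
  list(r = cor(pw, sp), n_windows = n_win, power = pw, speed = sp)
}

#' Linear interpolator from a track's speed series
#'
#' Helper producing the `speed_fun` used by the LFP-level detectors:
#' constant extrapolation outside the track's time range.
#'
#' @param track A [gs_track()].
#' @return Function mapping times (s) to speed (cm/s).
#' @export
speed_interpolator <- function(track) {
  v <- track$velocity; tt <- track$times
  function(times) {
    out <- approx(tt, v, xout = times, rule = 2)$y
    out
  }
}
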