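#' Rayleigh test for circular uniformity
#'
#' Tests whether a sample of angles deviates from the uniform circular
#' distribution, using the standard refined approximation of the Rayleigh
#' p value.
#'
#' @param angles Radians.
#' @return List with `r_bar` (mean resultant length), `n`, `p`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  r_bar <- Mod(mean(exp(1i * angles)))
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r_bar = r_bar, n = n, p = min(1, p))
}

#' Maximum-likelihood von Mises concentration
#'
#' Estimates kappa by inverting `A1(kappa) = r_bar` with the standard
#' piecewise approximation (Fisher), and the preferred direction as the
#' circular mean.
#'
#' @param angles Radians.
#' @return List with `kappa` and `mu` (radians).
#' @export
vonmises_fit <- function(angles) {
  z <- mean(exp(1i * angles))
  r <- Mod(z)
  kappa <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
  list(kappa = kappa, mu = Arg(z))
}

#' Theta phase locking of a single unit
#'
#' Spikes are restricted to valid theta cycles (and outside the SWR mask);
#' each spike is assigned the reference theta phase at its time. Units with
#' fewer than 50 in-cycle spikes are excluded. Deviation from circular
#' uniformity is tested with the Rayleigh test; for significantly locked
#' units (p < 0.05) the von Mises concentration kappa and preferred phase
#' are estimated.
#'
#' @param unit A [gs_unit()].
#' @param cycles Data frame from [detect_theta_cycles()].
#' @param theta_phase Phase vector over the whole LFP (radians).
#' @param fs LFP sampling rate, Hz.
#' @param min_spikes Inclusion threshold.
#' @return A `gs_phase_locking` list (`n_spikes`, `rayleigh_p`, `kappa`,
#'   `preferred_phase_deg`, `phases`) or `NULL` when excluded.
#' @export
theta_phase_locking <- function(unit, cycles, theta_phase, fs = LFP_FS,
                                min_spikes = 50) {
  st <- unit$spike_times
  if (nrow(cycles) == 0 || length(st) == 0) return(NULL)
  keep <- rep(FALSE, length(st))
  ci <- findInterval(st, cycles$start_s)
  ok <- ci >= 1 & ci <= nrow(cycles)
  keep[ok] <- st[ok] <= cycles$end_s[pmax(ci[ok], 1)]
  st <- st[keep]
  if (length(st) < min_spikes) return(NULL)
  idx <- pmin(pmax(round(st * fs) + 1, 1), length(theta_phase))
  ph <- theta_phase[idx]
  rt <- rayleigh_test(ph)
  out <- list(n_spikes = length(ph), rayleigh_p = rt$p, kappa = NA_real_,
              preferred_phase_deg = NA_real_, phases = ph)
  if (rt$p < 0.05) {
    vm <- vonmises_fit(ph)
    out$kappa <- vm$kappa
    out$preferred_phase_deg <- (vm$mu * 180 / pi) %% 360
  }
  structure(out, class = "gs_phase_locking")
}

spikes_to_bins <- function(times, t0, t1, swr_mask_fun = NULL) {
  st <- times[times >= t0 & times < t1]
  if (!is.null(swr_mask_fun)) st <- st[!swr_mask_fun(st)]
  unique(as.integer(floor((st - t0) * 1000)))
}

#' Normalized cross-correlogram and short-latency excess strength
#'
#' Both trains are binarized at 1 ms; the CCG counts, for each lag in
#' -50..50 ms, target bins containing a spike at that lag from each
#' reference spike, normalized by the number of reference spikes in the
#' analysis window. Baseline is the mean normalized CCG at absolute lags
#' 20-50 ms (both sides); the excess CCG subtracts it. Coordination
#' strength is the maximum excess within 1-3 ms (within-region pairs) or
#' 1-5 ms (cross-region pairs); both end lags inclusive.
#'
#' @param ref_spikes,target_spikes Spike times in seconds.
#' @param window `c(start_s, end_s)` analysis window (e.g., one block).
#' @param cross_region Use the 1-5 ms strength window.
#' @param swr_mask_fun Optional function: spike times -> logical (TRUE for
#'   spikes inside the SWR exclusion mask).
#' @return A `gs_pair_ccg` list: `lags` (-50..50), `ccg_norm`, `baseline`,
#'   `excess`, `strength`, `n_ref`, plus bookkeeping used by
#'   [jitter_null()].
#' @export
ccg_excess <- function(ref_spikes, target_spikes, window,
                       cross_region = FALSE, swr_mask_fun = NULL) {
  t0 <- window[1]; t1 <- window[2]
  ref_bins <- spikes_to_bins(ref_spikes, t0, t1, swr_mask_fun)
  targ_bins <- spikes_to_bins(target_spikes, t0, t1, swr_mask_fun)
  n_bins <- as.integer(ceiling((t1 - t0) * 1000))
  if (length(ref_bins) == 0) return(NULL)
  counts <- ccg_counts_cpp(ref_bins, targ_bins, n_bins, 50L)
  ccg_norm <- counts / length(ref_bins)
  lags <- -50:50
  base_sel <- abs(lags) >= 20 & abs(lags) <= 50
  baseline <- mean(ccg_norm[base_sel])
  excess <- ccg_norm - baseline
  win <- if (cross_region) 1:5 else 1:3
  strength <- max(excess[lags %in% win])
  structure(list(lags = lags, ccg_norm = ccg_norm, baseline = baseline,
                 excess = excess, strength = strength,
                 n_ref = length(ref_bins), window = c(t0, t1),
                 win_lags = win, ref_bins = ref_bins,
                 targ_bins = targ_bins, n_bins = n_bins),
            class = "gs_pair_ccg")
}

#' Jittered-surrogate empirical p value for a pair
#'
#' Each surrogate shifts every target spike by an independent integer
#' offset uniform on -25..25 ms (re-binarized after jittering) and
#' recomputes the same short-latency strength; the one-sided empirical p
#' is `(1 + #\{T_k >= T_obs\}) / (1 + N_surr)`, bounded below by
#' `1/(N_surr + 1)`.
#'
#' @param pair A `gs_pair_ccg` from [ccg_excess()].
#' @param n_surr Number of surrogates (1,000).
#' @param jitter_ms Maximum absolute offset, ms.
#' @param seed Optional integer seed for the surrogate RNG (derive one per
#'   pair and block from a master seed for reproducibility).
#' @return List with `p_emp`, `t_obs`, `null` (surrogate strengths).
#' @export
jitter_null <- function(pair, n_surr = 1000, jitter_ms = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  null <- jitter_null_cpp(pair$ref_bins, pair$targ_bins, pair$n_bins, 50L,
                          as.integer(jitter_ms),
                          min(pair$win_lags), max(pair$win_lags),
                          as.integer(n_surr))
  p <- (1 + sum(null >= pair$strength)) / (1 + n_surr)
  list(p_emp = p, t_obs = pair$strength, null = null)
}

#' Benjamini-Hochberg correction within reference-neuron groups
#'
#' All pairs sharing one reference neuron (within a block) form one
#' correction family; standard BH step-up is applied within each family at
#' level `q`.
#'
#' @param pvals Numeric p values.
#' @param ref_ids Grouping vector (reference neuron of each pair).
#' @param q FDR level.
#' @return Logical significance flags, same order as `pvals`.
#' @export
fdr_by_reference <- function(pvals, ref_ids, q = 0.05) {
  sig <- logical(length(pvals))
  for (g in unique(ref_ids)) {
    idx <- which(ref_ids == g)
    sig[idx] <- p.adjust(pvals[idx], method = "BH") < q
  }
  sig
}

#' Classify the learning trend of a pair's coordination strength
#'
#' beta is the OLS slope of strength against block number (1..4); Delta is
#' the Block 4 minus Block 1 difference. A pair is `increased` iff beta > 0
#' and Delta > 0, `decreased` iff beta < 0 and Delta < 0, otherwise
#' `unclassified` (including any missing block).
#'
#' @param strengths Numeric vector of four block strengths (B1..B4).
#' @return List with `trend`, `beta`, `delta`.
#' @export
classify_trend <- function(strengths) {
  if (length(strengths) != 4 || any(!is.finite(strengths)))
    return(list(trend = "unclassified", beta = NA_real_, delta = NA_real_))
  x <- 1:4
  beta <- coef(lm(strengths ~ x))[[2]]
  delta <- strengths[4] - strengths[1]
  trend <- if (beta > 0 && delta > 0) "increased"
  else if (beta < 0 && delta < 0) "decreased"
  else "unclassified"
  list(trend = trend, beta = beta, delta = delta)
}

#' Session-level pair counts by trend and reorganization label
#'
#' Each significant pair contributes to the count of its trend class under
#' the reorganization label of its first (reference) neuron, split by
#' direction (dCA1->mOFC, mOFC->dCA1, or within-region). Pairs whose
#' reference unit is unlabeled are excluded.
#'
#' @param pairs Data frame with `ref_id`, `target_id`, `ref_region`,
#'   `target_region`, `trend`, `significant`.
#' @param labels Data frame with `unit_id` and logical `reorganization`.
#' @return Data frame of counts per direction x trend x label.
#' @export
reorganization_pair_counts <- function(pairs, labels) {
  sig <- pairs[pairs$significant & pairs$trend != "unclassified", ,
               drop = FALSE]
  lab <- labels$reorganization[match(sig$ref_id, labels$unit_id)]
  keep <- !is.na(lab)
  sig <- sig[keep, , drop = FALSE]; lab <- lab[keep]
  if (nrow(sig) == 0)
    return(data.frame(direction = character(0), trend = character(0),
                      label = character(0), n = integer(0)))
  direction <- ifelse(sig$ref_region == sig$target_region,
                      paste0("within_", sig$ref_region),
                      paste0(sig$ref_region, "->", sig$target_region))
  out <- as.data.frame(table(direction = direction, trend = sig$trend,
                             label = ifelse(lab, "reorganization",
                                            "non_reorganization")))
  names(out)[4] <- "n"
  out
}

#' Full pairwise short-latency coordination pipeline over blocks
#'
#' For every ordered unit pair: per-block excess-CCG strength, jittered
#' surrogate p value in the final block comparison window, per-reference BH
#' correction within blocks, and a learning-trend class from the four block
#' strengths.
#'
#' @param units List of [gs_unit()]s.
#' @param blocks Data frame with `start_s`, `end_s`, one row per block.
#' @param n_surr Surrogates per pair and block.
#' @param master_seed Master seed; per (pair, block) seeds are derived from
#'   it deterministically.
#' @param swr_mask_fun Optional SWR exclusion function (times -> logical).
#' @param max_pairs Optional cap on the number of ordered pairs (for
#'   bounded runtimes on large sessions).
#' @return Data frame with one row per ordered pair: per-block strengths,
#'   minimum block p, significance in any block, trend, beta, delta.
#' @export
pair_coordination <- function(units, blocks, n_surr = 1000,
                              master_seed = 1, swr_mask_fun = NULL,
                              max_pairs = Inf) {
  n <- length(units)
  rows <- list()
  pair_idx <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    pair_idx <- pair_idx + 1
    if (pair_idx > max_pairs) break
    ua <- units[[a]]; ub <- units[[b]]
    cross <- ua$region != ub$region
    strengths <- rep(NA_real_, nrow(blocks))
    pvals <- rep(NA_real_, nrow(blocks))
    for (bl in seq_len(nrow(blocks))) {
      cc <- ccg_excess(ua$spike_times, ub$spike_times,
                       c(blocks$start_s[bl], blocks$end_s[bl]),
                       cross_region = cross, swr_mask_fun = swr_mask_fun)
      if (is.null(cc)) next
      strengths[bl] <- cc$strength
      seed <- (master_seed * 1000003L + pair_idx * 101L + bl) %% .Machine$integer.max
      pvals[bl] <- jitter_null(cc, n_surr = n_surr, seed = seed)$p_emp
    }
    tr <- classify_trend(strengths)
    rows[[length(rows) + 1]] <- data.frame(
      ref_id = ua$unit_id, target_id = ub$unit_id,
      ref_region = ua$region, target_region = ub$region,
      ref_type = ua$cell_type, target_type = ub$cell_type,
      t(setNames(strengths, paste0("strength_b", seq_len(nrow(blocks))))),
      t(setNames(pvals, paste0("p_b", seq_len(nrow(blocks))))),
      beta = tr$beta, delta = tr$delta, trend = tr$trend,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  # per-block BH within reference-neuron families
  sig_any <- rep(FALSE, nrow(res))
  for (bl in seq_len(nrow(blocks))) {
    p <- res[[paste0("p_b", bl)]]
    ok <- !is.na(p)
    flags <- rep(FALSE, nrow(res))
    if (any(ok)) flags[ok] <- fdr_by_reference(p[ok], res$ref_id[ok])
    res[[paste0("sig_b", bl)]] <- flags
    sig_any <- sig_any | flags
  }
  res$significant <- sig_any
  res
}
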