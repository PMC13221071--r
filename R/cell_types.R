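#' Classify a unit into a putative cell type
#'
#' Two-parameter waveform/autocorrelogram rule: units with a trough-to-peak
#' latency of at most 0.425 ms are putative narrow-waveform interneurons;
#' of the remainder, units whose autocorrelogram rise time constant
#' (`acg_tau_rise`) exceeds 6 ms are putative wide-waveform interneurons;
#' everything else is a putative pyramidal cell. The rule is a total
#' function partitioning the metric plane into exactly three regions, with
#' inclusive/exclusive boundaries as written (`<=` 0.425, `>` 6).
#'
#' @param trough_to_peak Spike waveform trough-to-peak latency in ms.
#' @param acg_tau_rise Autocorrelogram rise time constant in ms.
#' @return One of `"narrow_interneuron"`, `"wide_interneuron"`,
#'   `"pyramidal"`. Vectorized over both arguments.
#' @export
classify_cell_type <- function(trough_to_peak, acg_tau_rise) {
  if (length(trough_to_peak) != length(acg_tau_rise))
    stop("trough_to_peak and acg_tau_rise must have equal length")
  if (any(!is.finite(trough_to_peak)) || any(!is.finite(acg_tau_rise)))
    stop("invalid cell-type metric: non-finite value")
  if (any(trough_to_peak <= 0) || any(acg_tau_rise <= 0))
    stop("invalid cell-type metric: values must be positive")
  ifelse(trough_to_peak <= 0.425, "narrow_interneuron",
         ifelse(acg_tau_rise > 6, "wide_interneuron", "pyramidal"))
}

#' Filter units by mean firing rate
#'
#' Keeps units whose session-wide mean rate is at least `min_rate` Hz
#' (inclusive bound), preserving input order.
#'
#' @param units List of `gs_unit` objects.
#' @param min_rate Minimum mean firing rate in Hz (default 0.3).
#' @return Filtered list of units.
#' @export
filter_units <- function(units, min_rate = 0.3) {
  stopifnot(min_rate >= 0)
  units[vapply(units, function(u) u$mean_rate >= min_rate, logical(1))]
}
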