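#' Bin spike trains and z-score per neuron
#'
#' Spike counts in 20-ms bins over the analysis window; bins that touch a
#' detected sharp-wave ripple or the 100 ms that follow one are removed
#' before z-scoring. Neurons with zero count variance over the retained
#' bins are dropped with a warning.
#'
#' @param units List of [gs_unit()]s (or numeric spike-time vectors).
#' @param window `c(start_s, end_s)`.
#' @param bin_s Bin width, s.
#' @param swr_events Optional data frame with `start_s`, `end_s`.
#' @param min_bins Minimum usable bin count.
#' @return List with `z` (neurons x bins matrix), `kept` (indices of
#'   retained neurons), `bin_times` (bin start times).
#' @export
bin_and_zscore <- function(units, window, bin_s = 0.02, swr_events = NULL,
                           min_bins = 100) {
  spikes <- lapply(units, function(u)
    if (is.list(u)) u$spike_times else u)
  edges <- seq(window[1], window[2], by = bin_s)
  if (length(edges) < 2) stop("window too short")
  nb <- length(edges) - 1
  counts <- t(vapply(spikes, function(st) {
    st <- st[st >= window[1] & st < edges[nb + 1]]
    tabulate(findInterval(st, edges, rightmost.closed = FALSE), nb)
  }, numeric(nb)))
  keep_bins <- rep(TRUE, nb)
  if (!is.null(swr_events) && nrow(swr_events)) {
    for (i in seq_len(nrow(swr_events))) {
      bad <- edges[-(nb + 1)] < swr_events$end_s[i] + 0.1 &
        edges[-1] > swr_events$start_s[i]
      keep_bins[bad] <- FALSE
    }
  }
  counts <- counts[, keep_bins, drop = FALSE]
  if (ncol(counts) < min_bins) stop("fewer than ", min_bins, " usable bins")
  sds <- apply(counts, 1, sd)
  kept <- which(sds > 0)
  if (length(kept) < length(spikes))
    warning(sprintf("dropped %d zero-variance neuron(s)",
                    length(spikes) - length(kept)))
  z <- (counts[kept, , drop = FALSE] - rowMeans(counts[kept, , drop = FALSE])) /
    sds[kept]
  list(z = z, kept = kept, bin_times = edges[-(nb + 1)][keep_bins])
}

#' Count Marchenko-Pastur-significant components
#'
#' Eigendecomposition of the neuron-by-neuron correlation matrix of the
#' z-scored binned activity; components whose eigenvalue exceeds the
#' Marchenko-Pastur upper edge `(1 + sqrt(n/T))^2` (unit-variance data)
#' carry more correlation than expected from independent neurons.
#'
#' @param z Neurons x bins z-scored matrix.
#' @return List with `n_significant`, `threshold`, `eigenvalues`,
#'   `vectors`.
#' @export
mp_significant_components <- function(z) {
  n <- nrow(z); T <- ncol(z)
  C <- tcrossprod(z) / T
  if (any(!is.finite(C))) stop("degenerate correlation matrix")
  eg <- eigen(C, symmetric = TRUE)
  thr <- (1 + sqrt(n / T))^2
  list(n_significant = sum(eg$values > thr), threshold = thr,
       eigenvalues = eg$values, vectors = eg$vectors)
}

# FastICA with symmetric decorrelation and the logcosh contrast, run on
# pre-whitened data (rows = components, cols = samples)
fastica_symm <- function(xw, n_comp, max_iter = 500, tol = 1e-8,
                         seed = 1) {
  set.seed(seed)
  k <- nrow(xw); T <- ncol(xw)
  W <- matrix(rnorm(n_comp * k), n_comp, k)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    wx <- W %*% xw
    g <- tanh(wx)
    gp <- 1 - g^2
    W1 <- (g %*% t(xw)) / T - diag(rowMeans(gp), n_comp) %*% W
    W1 <- sym_decor(W1)
    if (max(abs(abs(rowSums(W1 * W)) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  W
}

#' Extract assembly patterns via PCA subspace + ICA
#'
#' The z-scored activity is projected onto the Marchenko-Pastur-significant
#' principal subspace, whitened, and unmixed with FastICA (logcosh,
#' symmetric decorrelation, deterministic seed). Each component's weight
#' vector is mapped back to neuron space, normalized to unit length, and
#' sign-fixed so the largest-magnitude weight is positive.
#'
#' @param z Neurons x bins z-scored matrix.
#' @param n_components Number of assemblies (from
#'   [mp_significant_components()]); 0 returns an empty list.
#' @param seed ICA seed.
#' @return List of `gs_assembly` objects with `weights` (unit vector over
#'   neurons) and `projection` (outer product with zero diagonal).
#' @export
extract_assemblies <- function(z, n_components, seed = 1) {
  if (n_components == 0) return(list())
  mp <- mp_significant_components(z)
  k <- n_components
  V <- mp$vectors[, seq_len(k), drop = FALSE]
  lam <- mp$eigenvalues[seq_len(k)]
  xw <- diag(1 / sqrt(lam), k) %*% t(V) %*% z  # whitened subspace signals
  W <- fastica_symm(xw, k, seed = seed)
  lapply(seq_len(k), function(i) {
    # mixing column in neuron space for independent component i
    w <- V %*% diag(sqrt(lam), k) %*% W[i, ]
    w <- as.numeric(w)
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    P <- tcrossprod(w)
    diag(P) <- 0
    structure(list(weights = w, projection = P), class = "gs_assembly")
  })
}

#' Assembly activation strength and discrete events
#'
#' `S(t) = z(t)' P z(t)` per 20-ms bin with the projection diagonal zeroed,
#' so isolated spiking of a single neuron contributes nothing. Events are
#' strict local maxima of S exceeding the threshold (plateau ties take the
#' first bin).
#'
#' @param pattern A `gs_assembly` from [extract_assemblies()].
#' @param z Neurons x bins z-scored matrix.
#' @param threshold Event threshold on S.
#' @return List with `activation` (S per bin) and `events` (bin indices).
#' @export
activation_events <- function(pattern, z, threshold = 5) {
  P <- pattern$projection
  S <- colSums((P %*% z) * z)
  n <- length(S)
  if (n < 3) return(list(activation = S, events = integer(0)))
  is_peak <- c(FALSE, S[2:(n - 1)] > S[1:(n - 2)] & S[2:(n - 1)] > S[3:n],
               FALSE)
  list(activation = S, events = which(is_peak & S > threshold))
}
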