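#include <Rcpp.h>
using namespace Rcpp;

// Cross-correlogram machinery on 1-ms binarized spike trains.
// Trains arrive as integer bin indices (ms); binarization (>=1 spike per
// bin -> 1) is enforced here by deduplication against a stamp array, so
// jittered surrogates that collide in one bin collapse to a single count.

static void ccg_accumulate(const std::vector<int>& ref,
                           const int* targ_stamp, int stamp_id,
                           int n_bins, int max_lag,
                           std::vector<double>& counts) {
  for (size_t i = 0; i < ref.size(); ++i) {
    int r = ref[i];
    int lo = std::max(0, r - max_lag), hi = std::min(n_bins - 1, r + max_lag);
    for (int b = lo; b <= hi; ++b)
      if (targ_stamp[b] == stamp_id) counts[b - r + max_lag] += 1.0;
  }
}

// [[Rcpp::export]]
NumericVector ccg_counts_cpp(IntegerVector ref_bins, IntegerVector targ_bins,
                             int n_bins, int max_lag) {
  std::vector<int> stamp(n_bins, -1);
  for (int i = 0; i < targ_bins.size(); ++i) {
    int b = targ_bins[i];
    if (b >= 0 && b < n_bins) stamp[b] = 0;
  }
  std::vector<int> ref;
  std::vector<int> seen(n_bins, -1);
  for (int i = 0; i < ref_bins.size(); ++i) {
    int b = ref_bins[i];
    if (b >= 0 && b < n_bins && seen[b] != 0) { seen[b] = 0; ref.push_back(b); }
  }
  std::vector<double> counts(2 * max_lag + 1, 0.0);
  ccg_accumulate(ref, stamp.data(), 0, n_bins, max_lag, counts);
  return wrap(counts);
}

static double strength_from_counts(const std::vector<double>& counts,
                                   int max_lag, double n_ref,
                                   int win_lo, int win_hi) {
  double base = 0.0; int nb = 0;
  for (int lag = -max_lag; lag <= max_lag; ++lag) {
    int a = std::abs(lag);
    if (a >= 20 && a <= 50) { base += counts[lag + max_lag] / n_ref; ++nb; }
  }
  base /= nb;
  double best = R_NegInf;
  for (int lag = win_lo; lag <= win_hi; ++lag) {
    double v = counts[lag + max_lag] / n_ref - base;
    if (v > best) best = v;
  }
  return best;
}

// Jittered-surrogate null: every target spike shifted by an independent
// integer offset uniform on [-jitter, jitter] ms, re-binarized, and the
// same short-latency strength recomputed. Uses R's RNG (honors set.seed).
// [[Rcpp::export]]
NumericVector jitter_null_cpp(IntegerVector ref_bins, IntegerVector targ_bins,
                              int n_bins, int max_lag, int jitter,
                              int win_lo, int win_hi, int n_surr) {
  std::vector<int> ref;
  {
    std::vector<int> seen(n_bins, -1);
    for (int i = 0; i < ref_bins.size(); ++i) {
      int b = ref_bins[i];
      if (b >= 0 && b < n_bins && seen[b] != 0) { seen[b] = 0; ref.push_back(b); }
    }
  }
  double n_ref = (double)ref.size();
  NumericVector out(n_surr);
  std::vector<int> stamp(n_bins, -1);
  std::vector<double> counts(2 * max_lag + 1);
  for (int k = 0; k < n_surr; ++k) {
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int i = 0; i < targ_bins.size(); ++i) {
      int off = (int)std::floor(unif_rand() * (2 * jitter + 1)) - jitter;
      if (off > jitter) off = jitter;  // guard against unif_rand()==1
      int b = targ_bins[i] + off;
      if (b >= 0 && b < n_bins) stamp[b] = k;
    }
    ccg_accumulate(ref, stamp.data(), k, n_bins, max_lag, counts);
    out[k] = strength_from_counts(counts, max_lag, n_ref, win_lo, win_hi);
  }
  return out;
}
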