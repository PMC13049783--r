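#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections, direct form II transposed.
// sos: k x 6 matrix with rows (b0, b1, b2, a0, a1, a2); a0 must be 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int n = x.size(), k = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Hysteresis segmentation on an envelope: a phase opens when v rises above
// hi and closes when it falls below lo (both per-frame thresholds).
// Returns a 2-column matrix of (start, end) frame indices (1-based, inclusive).
// [[Rcpp::export]]
IntegerMatrix hysteresis_runs_cpp(NumericVector v, NumericVector hi, NumericVector lo) {
  const int n = v.size();
  std::vector<int> starts, ends;
  bool open = false;
  int s0 = 0;
  for (int i = 0; i < n; ++i) {
    if (!open) {
      if (v[i] > hi[i]) { open = true; s0 = i; }
    } else if (v[i] < lo[i]) {
      starts.push_back(s0 + 1);
      ends.push_back(i);  // last frame still above lo is i-1; use i as exclusive-ish end-1
      open = false;
    }
  }
  if (open) { starts.push_back(s0 + 1); ends.push_back(n); }
  const int m = starts.size();
  IntegerMatrix out(m, 2);
  for (int j = 0; j < m; ++j) { out(j, 0) = starts[j]; out(j, 1) = ends[j]; }
  return out;
}
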