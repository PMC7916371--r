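#include <Rcpp.h>
using namespace Rcpp;

// Causal cascade of biquad sections (direct form II transposed), zero
// initial conditions. `sos` has one row per section: b0 b1 b2 a1 a2
// (leading denominator coefficient 1). First-order sections are encoded
// with b2 = a2 = 0.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int n = x.size(), ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 3), a2 = sos(s, 4);
    double w1 = 0.0, w2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
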