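#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed.
// sos: nsec x 5 matrix (b0, b1, b2, a1, a2), a0 = 1 implied.
// zi:  nsec x 2 initial conditions (or empty for zero state).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  int nsec = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  bool use_zi = zi.nrow() == nsec;
  for (int s = 0; s < nsec; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 3), a2 = sos(s, 4);
    double z1 = use_zi ? zi(s, 0) : 0.0;
    double z2 = use_zi ? zi(s, 1) : 0.0;
    for (int t = 0; t < n; ++t) {
      double xt = y[t];
      double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}
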