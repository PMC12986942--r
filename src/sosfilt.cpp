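#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads in transposed direct form II. sos has one section
// per row (b0 b1 b2 a0 a1 a2, a0 == 1); zi holds two initial state
// values per section and is consumed as given (zero it for a cold
// start).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x,
                          NumericMatrix zi) {
  int ns = sos.nrow();
  R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (R_xlen_t i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
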