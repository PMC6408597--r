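#include <Rcpp.h>
using namespace Rcpp;

// Height-field stacking primitives. `field` is a matrix indexed
// [ix, iy] (x along rows); cell indices are 1-based and assumed valid.

//' @noRd
// [[Rcpp::export]]
double cpp_footprint_max(const NumericMatrix& field, const IntegerVector& ix,
                         const IntegerVector& iy) {
  double m = 0.0;
  int n = ix.size();
  for (int k = 0; k < n; ++k) {
    double v = field(ix[k] - 1, iy[k] - 1);
    if (v > m) m = v;
  }
  return m;
}

// Raise the field to max(field, rest + ztop) under the footprint.
// Modifies `field` in place (the caller owns a private copy).
//' @noRd
// [[Rcpp::export]]
void cpp_footprint_raise(NumericMatrix field, const IntegerVector& ix,
                         const IntegerVector& iy, const NumericVector& ztop,
                         double rest) {
  int n = ix.size();
  for (int k = 0; k < n; ++k) {
    double v = rest + ztop[k];
    if (v > field(ix[k] - 1, iy[k] - 1)) field(ix[k] - 1, iy[k] - 1) = v;
  }
}
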