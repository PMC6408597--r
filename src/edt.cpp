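#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher 2012,
// lower-envelope-of-parabolas algorithm).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  const double BIG = 1e18;
  NumericMatrix D(nr, nc);
  // columns first
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = feature(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) D(i, j) = d[i];
  }
  // then rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = D(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) D(i, j) = std::sqrt(d[j]);
  }
  return D;
}
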