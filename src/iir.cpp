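#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. Coefficients must be normalized so
// that a[0] == 1. zi holds the initial state (length = length(b) - 1).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int m = b.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k + 2 < m; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
  return y;
}
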