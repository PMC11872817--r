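#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Direct form II transposed IIR filter with initial state zi (length
// max(na, nb) - 1). The workhorse behind filtfilt(); a[0] must be 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector x, NumericVector b,
                             NumericVector a, NumericVector zi) {
  int n = x.size(), nb = b.size(), na = a.size();
  int nz = std::max(na, nb) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), nz); i++) z[i] = zi[i];
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; i++) bb[i] = b[i];
  for (int i = 0; i < na; i++) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; i++) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; j++)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
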