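#include <Rcpp.h>
using namespace Rcpp;

// Binned-variance entropy profile: for each interval length L, one minus
// the ratio of summed within-interval population variances to M times the
// full-series population variance (remainder samples dropped).
// [[Rcpp::export]]
NumericVector entropy_profile_cpp(NumericVector x, IntegerVector lengths) {
  int n = x.size();
  double mu = 0.0, m2 = 0.0;
  for (int i = 0; i < n; i++) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; i++) m2 += (x[i] - mu) * (x[i] - mu);
  double sigma2 = m2 / n;
  if (sigma2 <= 0.0) stop("entropy undefined for a constant series");
  int nl = lengths.size();
  NumericVector out(nl);
  for (int li = 0; li < nl; li++) {
    int L = lengths[li];
    if (L < 1 || L > n) stop("interval length out of range");
    int M = n / L;
    double acc = 0.0;
    for (int j = 0; j < M; j++) {
      double s = 0.0, ss = 0.0;
      const double *p = &x[j * L];
      for (int k = 0; k < L; k++) { s += p[k]; ss += p[k] * p[k]; }
      acc += (ss - s * s / L) / L;
    }
    out[li] = 1.0 - acc / (M * sigma2);
  }
  return out;
}
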