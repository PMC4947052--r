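#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state.
// b, a are coefficient vectors with a[0] == 1 (normalized by the caller).
// zi has length max(len(a), len(b)) - 1 and follows the scipy lfilter
// state convention, so steady-state initial conditions computed in R can
// be passed straight through for zero-phase (forward-backward) filtering.
// [[Rcpp::export(name = ".cpp_iir_filter")]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  int n = x.size();
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nfilt, 0.0);
  for (int i = 0; i < (int)zi.size() && i < nfilt - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nfilt - 1; ++j)
      z[j] = bb[j + 1] * xi - aa[j + 1] * yi + z[j + 1];
    y[i] = yi;
  }
  return y;
}
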