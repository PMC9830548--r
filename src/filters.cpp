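#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter. Coefficients normalised so a[0] == 1
// upstream; state starts at zero (padding is handled by the R wrapper).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> w(nw, 0.0);
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int j = 0; j < nw - 1; ++j)
      w[j] = bb[j + 1] * xi + w[j + 1] - aa[j + 1] * yi;
    if (nw > 0) w[nw - 1] = bb[nw] * xi - aa[nw] * yi;
    y[i] = yi;
  }
  return y;
}
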