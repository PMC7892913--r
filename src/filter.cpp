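// Zero-phase FIR filtering of an epoched array (trials x channels x time,
// column-major as stored by R). Each series is reflection-padded, convolved
// with the symmetric odd-length kernel b, and read out with the group delay
// compensated, giving exactly zero phase shift.

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::NumericVector fir_zerophase_cpp(Rcpp::NumericVector x,
                                      Rcpp::IntegerVector dims,
                                      Rcpp::NumericVector b) {
  const int ntr = dims[0], nch = dims[1], nt = dims[2];
  const int lb = b.size();
  const int delay = (lb - 1) / 2;
  const int pad = std::min(3 * lb, nt - 1);
  const R_xlen_t plane = (R_xlen_t)ntr * nch;

  Rcpp::NumericVector out(x.size());
  out.attr("dim") = dims;
  std::vector<double> s(nt), xs(nt + 2 * pad);
  const double* xp = x.begin();
  double* op = out.begin();
  const double* bp = b.begin();

  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < ntr; ++i) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)c * ntr;
      for (int t = 0; t < nt; ++t) s[t] = xp[base + (R_xlen_t)t * plane];
      for (int p = 0; p < pad; ++p) {
        // odd reflection keeps value and slope continuous at the edges
        xs[p] = 2.0 * s[0] - s[pad - p];
        xs[pad + nt + p] = 2.0 * s[nt - 1] - s[nt - 2 - p];
      }
      for (int t = 0; t < nt; ++t) xs[pad + t] = s[t];
      for (int t = 0; t < nt; ++t) {
        const double* w = &xs[pad + t + delay];
        double acc = 0.0;
        for (int l = 0; l < lb; ++l) acc += bp[l] * w[-l];
        op[base + (R_xlen_t)t * plane] = acc;
      }
    }
  }
  return out;
}
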