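#include <Rcpp.h>
using namespace Rcpp;

// Cascaded-biquad (second-order-sections) IIR filter, direct form II
// transposed. sos rows are (b0, b1, b2, a0, a1, a2) with a0 == 1.
// [[Rcpp::export(name = ".sosfilt")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Normalized LMS adaptive filter: y is the primary channel, X the lagged
// reference design (n x k). Returns the per-sample residual and the final
// weight vector. eps regularizes the per-sample normalization.
// [[Rcpp::export(name = ".nlms")]]
List nlms_cpp(NumericMatrix X, NumericVector y, double step, double eps) {
  const R_xlen_t n = X.nrow();
  const int k = X.ncol();
  NumericVector w(k), e(n);
  std::vector<double> xi(k);
  for (R_xlen_t t = 0; t < n; ++t) {
    double yhat = 0.0, nrm = eps;
    for (int j = 0; j < k; ++j) {
      xi[j] = X(t, j);
      yhat += w[j] * xi[j];
      nrm += xi[j] * xi[j];
    }
    const double err = y[t] - yhat;
    e[t] = err;
    const double g = step * err / nrm;
    for (int j = 0; j < k; ++j) w[j] += g * xi[j];
  }
  return List::create(_["weights"] = w, _["residual"] = e);
}
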