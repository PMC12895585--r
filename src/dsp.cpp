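// Inner loops of the signal-processing stages: one level of the periodized
// orthogonal DWT analysis/synthesis bank and direct-form IIR filtering,
// both vectorized over the columns of a time x channel matrix.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List dwt_step_cpp(const NumericMatrix& x, const NumericVector& lo,
                  const NumericVector& hi) {
  const int n = x.nrow(), nc = x.ncol(), L = lo.size();
  const int half = n / 2;
  NumericMatrix a(half, nc), d(half, nc);
  for (int j = 0; j < nc; ++j) {
    const double* xj = &x(0, j);
    double* aj = &a(0, j);
    double* dj = &d(0, j);
    for (int k = 0; k < half; ++k) {
      double sa = 0.0, sd = 0.0;
      int base = 2 * k;
      for (int t = 0; t < L; ++t) {
        int p = base + t;
        if (p >= n) p -= n;  // periodic wrap (L < n always)
        double v = xj[p];
        sa += lo[t] * v;
        sd += hi[t] * v;
      }
      aj[k] = sa;
      dj[k] = sd;
    }
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// [[Rcpp::export]]
NumericMatrix idwt_step_cpp(const NumericMatrix& a, const NumericMatrix& d,
                            const NumericVector& lo, const NumericVector& hi) {
  const int half = a.nrow(), nc = a.ncol(), L = lo.size();
  const int n = 2 * half;
  NumericMatrix x(n, nc);
  for (int j = 0; j < nc; ++j) {
    const double* aj = &a(0, j);
    const double* dj = &d(0, j);
    double* xj = &x(0, j);
    for (int k = 0; k < half; ++k) {
      int base = 2 * k;
      double va = aj[k], vd = dj[k];
      for (int t = 0; t < L; ++t) {
        int p = base + t;
        if (p >= n) p -= n;
        xj[p] += lo[t] * va + hi[t] * vd;
      }
    }
  }
  return x;
}

// Direct-form-II-transposed IIR filter with per-column initial state
// zi * x[0, j] (filtfilt edge-transient handling). b and a must share length.
// [[Rcpp::export]]
NumericMatrix iir_filter_cpp(const NumericVector& b, const NumericVector& a,
                             const NumericMatrix& x, const NumericVector& zi) {
  const int n = x.nrow(), nc = x.ncol();
  const int nf = b.size();
  NumericVector bn = clone(b), an = clone(a);
  for (int i = 0; i < nf; ++i) { bn[i] /= a[0]; an[i] /= a[0]; }
  NumericMatrix y(n, nc);
  std::vector<double> z(nf - 1);
  for (int j = 0; j < nc; ++j) {
    const double* xj = &x(0, j);
    double* yj = &y(0, j);
    for (int i = 0; i < nf - 1; ++i) z[i] = zi[i] * xj[0];
    for (int t = 0; t < n; ++t) {
      double xt = xj[t];
      double yt = bn[0] * xt + z[0];
      for (int i = 0; i < nf - 2; ++i) {
        z[i] = bn[i + 1] * xt + z[i + 1] - an[i + 1] * yt;
      }
      z[nf - 2] = bn[nf - 1] * xt - an[nf - 1] * yt;
      yj[t] = yt;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector col_abs_median_cpp(const NumericMatrix& x) {
  const int n = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(n);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = std::fabs(x(i, j));
    int mid = n / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (n % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
      m = 0.5 * (m + buf[mid - 1]);
    }
    out[j] = m;
  }
  return out;
}
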