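#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter over a raw buffer.
// b and a are pre-padded to length nz + 1 with a[0] == 1.
static inline void iir_filter(const double* b, const double* a, int nz,
                              double* x, int n, double* z) {
  for (int j = 0; j < nz; ++j) z[j] = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 1; j < nz; ++j)
      z[j - 1] = z[j] + b[j] * xi - a[j] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering of each column of X.
// Columns are extended at both ends by odd reflection over 3x the filter
// order before filtering, which suppresses start-up transients.
// [[Rcpp::export]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  const int nz = std::max(b.size(), a.size()) - 1;
  if (nz < 1) stop("filter must have order >= 1");
  std::vector<double> bv(nz + 1, 0.0), av(nz + 1, 0.0);
  for (int j = 0; j < b.size(); ++j) bv[j] = b[j];
  for (int j = 0; j < a.size(); ++j) av[j] = a[j];
  if (av[0] == 0.0) stop("a[1] must be nonzero");
  if (av[0] != 1.0)
    for (int j = nz; j >= 0; --j) { bv[j] /= av[0]; av[j] /= av[0]; }
  const int npad = std::min(3 * nz, n - 1);
  const int len = n + 2 * npad;
  NumericMatrix Y(n, m);
  std::vector<double> buf(len), z(nz);
  for (int c = 0; c < m; ++c) {
    const double* xc = &X(0, c);
    for (int i = 0; i < npad; ++i) buf[i] = 2.0 * xc[0] - xc[npad - i];
    std::copy(xc, xc + n, buf.begin() + npad);
    for (int i = 0; i < npad; ++i)
      buf[npad + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
    iir_filter(bv.data(), av.data(), nz, buf.data(), len, z.data());
    std::reverse(buf.begin(), buf.end());
    iir_filter(bv.data(), av.data(), nz, buf.data(), len, z.data());
    std::reverse(buf.begin(), buf.end());
    std::copy(buf.begin() + npad, buf.begin() + npad + n, &Y(0, c));
  }
  return Y;
}
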