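#include <Rcpp.h>
using namespace Rcpp;

// Gather feature rows into im2col form. idx is (rows x K), 1-based row
// indices into F, 0 marking padding (contributes zeros).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix F, IntegerMatrix idx) {
  const int n = idx.nrow(), K = idx.ncol(), C = F.ncol();
  NumericMatrix X2(n, K * C);
  for (int k = 0; k < K; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      const double* fc = &F(0, c);
      double* out = &X2(0, (k * C + c));
      for (int i = 0; i < n; ++i) {
        const int s = ik[i];
        out[i] = s ? fc[s - 1] : 0.0;
      }
    }
  }
  return X2;
}

// Adjoint of cpp_im2col: scatter the gradient of the column matrix back to
// feature rows. G is (rows x K*C); column block k is gathered with the
// opposite spatial offset, i.e. idx column K - 1 - k.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix G, IntegerMatrix idx, int C) {
  const int n = idx.nrow(), K = idx.ncol();
  NumericMatrix dX(n, C);
  for (int k = 0; k < K; ++k) {
    const int* ik = &idx(0, K - 1 - k);
    for (int c = 0; c < C; ++c) {
      const double* gc = &G(0, (k * C + c));
      double* out = &dX(0, c);
      for (int i = 0; i < n; ++i) {
        const int s = ik[i];
        if (s) out[i] += gc[s - 1];
      }
    }
  }
  return dX;
}
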