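// 1D convolution kernels for the network layers.
// Signals are stored as cubes (length x channels x batch); convolutions use
// stride 1 with symmetric zero padding handled by boundary-splitting the
// kernel loop (no padded copies), so the output length equals the input
// length (kernel size must be odd). Weights are laid out offset-major:
// W is (C_out x k*C_in) and W[, j*C_in + c] multiplies input channel c at
// kernel offset j. A fused leaky-rectifier (slope 1 = linear, 0 = ReLU)
// follows each convolution.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// valid output-row range [t0, t1] for kernel offset j with pad p
static inline void row_range(int j, int p, int L, int& t0, int& t1) {
  t0 = std::max(0, p - j);
  t1 = L - 1 - std::max(0, j - p);
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k, double slope) {
  const int p = (k - 1) / 2;
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows;
  cube out(L, Cout, B);
  mat brow = repmat(b.t(), L, 1);
  for (int s = 0; s < B; ++s) {
    mat o = brow;
    const mat& xs = x.slice(s);
    for (int j = 0; j < k; ++j) {
      int t0, t1;
      row_range(j, p, L, t0, t1);
      if (t0 > t1) continue;
      o.rows(t0, t1) += xs.rows(t0 + j - p, t1 + j - p) *
        W.cols(j * Cin, (j + 1) * Cin - 1).t();
    }
    if (slope != 1.0) {
      o.transform([slope](double v) { return v > 0 ? v : slope * v; });
    }
    out.slice(s) = o;
  }
  return out;
}

// Backward through the fused activation; `out` is the forward output (the
// activation is monotone, so its sign recovers the pre-activation sign).
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& out, const arma::cube& dout, int k,
                      double slope) {
  const int p = (k - 1) / 2;
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows;
  cube dx(L, Cin, B, fill::zeros);
  mat dW(Cout, k * Cin, fill::zeros);
  vec db(Cout, fill::zeros);
  mat ds(L, Cout);
  for (int s = 0; s < B; ++s) {
    const mat& xs = x.slice(s);
    ds = dout.slice(s);
    if (slope != 1.0) {
      const mat& os = out.slice(s);
      for (uword i = 0; i < ds.n_elem; ++i) {
        if (os(i) <= 0) ds(i) *= slope;
      }
    }
    db += sum(ds, 0).t();
    mat& dxs = dx.slice(s);
    for (int j = 0; j < k; ++j) {
      int t0, t1;
      row_range(j, p, L, t0, t1);
      if (t0 > t1) continue;
      dxs.rows(t0 + j - p, t1 + j - p) +=
        ds.rows(t0, t1) * W.cols(j * Cin, (j + 1) * Cin - 1);
      dW.cols(j * Cin, (j + 1) * Cin - 1) +=
        ds.rows(t0, t1).t() * xs.rows(t0 + j - p, t1 + j - p);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
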