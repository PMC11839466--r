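// Hot path of the 1-D convolution layers: im2col gather, GEMM, and the
// column-to-input scatter of the backward pass. Supports grouped and
// dilated kernels via a precomputed row-index map (0 = zero padding).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// rows: N x k integer map; entry 0 means padding. X: N x Cin.
// W: (k * Cin/g) x Cout, output channels ordered by group, weight rows
// tap-major within the group's channels.
// [[Rcpp::export]]
List conv1d_fwd_cpp(const arma::mat& X, const IntegerMatrix& rows,
                    const arma::mat& W, const arma::vec& b, int groups) {
  const int N = X.n_rows, Cin = X.n_cols, k = rows.ncol();
  const int Cout = W.n_cols;
  const int cg = Cin / groups, og = Cout / groups;
  arma::mat out(N, Cout);
  arma::cube cols(N, k * cg, groups);
  for (int g = 0; g < groups; ++g) {
    arma::mat& cg_mat = cols.slice(g);
    for (int j = 0; j < k; ++j) {
      for (int c = 0; c < cg; ++c) {
        const int src_c = g * cg + c;
        double* dst = cg_mat.colptr(j * cg + c);
        const double* src = X.colptr(src_c);
        const int* r = &rows(0, j);
        for (int i = 0; i < N; ++i) {
          dst[i] = r[i] > 0 ? src[r[i] - 1] : 0.0;
        }
      }
    }
    out.cols(g * og, (g + 1) * og - 1) =
      cg_mat * W.cols(g * og, (g + 1) * og - 1);
  }
  out.each_row() += b.t();
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::mat& X, const arma::cube& cols,
                    const IntegerMatrix& rows, const arma::mat& W,
                    const arma::mat& dOut, int groups) {
  const int N = X.n_rows, Cin = X.n_cols, k = rows.ncol();
  const int Cout = W.n_cols;
  const int cg = Cin / groups, og = Cout / groups;
  arma::mat dW(W.n_rows, Cout, arma::fill::zeros);
  arma::mat dX(N, Cin, arma::fill::zeros);
  arma::vec db = arma::sum(dOut, 0).t();
  for (int g = 0; g < groups; ++g) {
    const arma::mat& cg_mat = cols.slice(g);
    const arma::mat dg = dOut.cols(g * og, (g + 1) * og - 1);
    dW.cols(g * og, (g + 1) * og - 1) = cg_mat.t() * dg;
    arma::mat dcols = dg * W.cols(g * og, (g + 1) * og - 1).t();
    // within one tap the index map is an injective shift: plain adds
    for (int j = 0; j < k; ++j) {
      for (int c = 0; c < cg; ++c) {
        double* dst = dX.colptr(g * cg + c);
        const double* src = dcols.colptr(j * cg + c);
        const int* r = &rows(0, j);
        for (int i = 0; i < N; ++i) {
          if (r[i] > 0) dst[r[i] - 1] += src[i];
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
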