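// 3x3x3 convolution (zero padding 1) on 3D grids, forward and backward.
// Activations are N x C matrices in column-major voxel order (x fastest),
// weights are (27*Cin) x Cout with rows grouped per input channel, offsets
// ordered x-fastest to match the R-side index cache.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3d(const mat& X, const int d1, const int d2, const int d3) {
  const int N = d1 * d2 * d3;
  const int Cin = X.n_cols;
  mat Xcol(N, 27 * Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int oz = -1; oz <= 1; ++oz) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          const int o = (oz + 1) * 9 + (oy + 1) * 3 + (ox + 1);
          double* dst = Xcol.colptr(c * 27 + o);
          const int k0 = std::max(0, -oz), k1 = std::min(d3, d3 - oz);
          const int j0 = std::max(0, -oy), j1 = std::min(d2, d2 - oy);
          const int i0 = std::max(0, -ox), i1 = std::min(d1, d1 - ox);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              const int src_base = (i0 + ox) + d1 * ((j + oy) + d2 * (k + oz));
              const int dst_base = i0 + d1 * (j + d2 * k);
              std::copy(xc + src_base, xc + src_base + (i1 - i0),
                        dst + dst_base);
            }
          }
        }
      }
    }
  }
  return Xcol;
}

// scatter-add the columns of dXcol back onto the input grid
static mat col2im3d(const mat& dXcol, const int d1, const int d2,
                    const int d3, const int Cin) {
  const int N = d1 * d2 * d3;
  mat dX(N, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dX.colptr(c);
    for (int oz = -1; oz <= 1; ++oz) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          const int o = (oz + 1) * 9 + (oy + 1) * 3 + (ox + 1);
          const double* src = dXcol.colptr(c * 27 + o);
          const int k0 = std::max(0, -oz), k1 = std::min(d3, d3 - oz);
          const int j0 = std::max(0, -oy), j1 = std::min(d2, d2 - oy);
          const int i0 = std::max(0, -ox), i1 = std::min(d1, d1 - ox);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              const int grid_base = (i0 + ox) + d1 * ((j + oy) + d2 * (k + oz));
              const int col_base = i0 + d1 * (j + d2 * k);
              const double* s = src + col_base;
              double* t = dxc + grid_base;
              for (int i = 0; i < i1 - i0; ++i) t[i] += s[i];
            }
          }
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat conv3d_fwd_cpp(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, const arma::ivec& dims) {
  mat Xcol = im2col3d(X, dims[0], dims[1], dims[2]);
  mat Y = Xcol * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd_cpp(const arma::mat& X, const arma::mat& W,
                          const arma::mat& dY, const arma::ivec& dims) {
  mat Xcol = im2col3d(X, dims[0], dims[1], dims[2]);
  mat dW = Xcol.t() * dY;
  vec db = sum(dY, 0).t();
  mat dXcol = dY * W.t();
  mat dX = col2im3d(dXcol, dims[0], dims[1], dims[2], X.n_cols);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
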