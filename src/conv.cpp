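// Hot kernels of the 2-D convolution layers: im2col + BLAS matrix products.
// Tensors follow the R layout (batch, height, width, channel), column-major.
// Kernel taps are ordered row-offset fastest within column offset, and the
// weight-matrix rows are tap-fastest within input channel -- identical to
// the R reference implementation in nn_layers.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather the im2col patch matrix (n x K2*C), n = B*H*W, 'same' padding
static void im2col(const double* x, int B, int H, int W, int C,
                   int kernel, int pad, arma::mat& cols) {
  const int n = B * H * W;
  int t = 0;
  for (int dx = 0; dx < kernel; ++dx) {
    for (int dy = 0; dy < kernel; ++dy, ++t) {
      const int oi = dy - pad;   // row offset
      const int oj = dx - pad;   // column offset
      for (int c = 0; c < C; ++c) {
        double* dst0 = cols.colptr(t + kernel * kernel * c);
        const double* src0 = x + (std::size_t)B * H * W * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + oj;
          double* dst = dst0 + (std::size_t)B * H * j;
          if (jj < 0 || jj >= W) {
            std::memset(dst, 0, sizeof(double) * (std::size_t)B * H);
            continue;
          }
          for (int i = 0; i < H; ++i) {
            const int ii = i + oi;
            double* d = dst + (std::size_t)B * i;
            if (ii < 0 || ii >= H) {
              std::memset(d, 0, sizeof(double) * B);
            } else {
              std::memcpy(d, src0 + (std::size_t)B * (ii + (std::size_t)H * jj),
                          sizeof(double) * B);
            }
          }
        }
      }
    }
  }
  (void)n;
}

// scatter-add the patch-matrix gradient back onto the input tensor
static void col2im(const arma::mat& dcols, int B, int H, int W, int C,
                   int kernel, int pad, double* dx) {
  int t = 0;
  for (int dxo = 0; dxo < kernel; ++dxo) {
    for (int dy = 0; dy < kernel; ++dy, ++t) {
      const int oi = dy - pad;
      const int oj = dxo - pad;
      for (int c = 0; c < C; ++c) {
        const double* src0 = dcols.colptr(t + kernel * kernel * c);
        double* dst0 = dx + (std::size_t)B * H * W * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + oj;
          if (jj < 0 || jj >= W) continue;
          const double* src = src0 + (std::size_t)B * H * j;
          for (int i = 0; i < H; ++i) {
            const int ii = i + oi;
            if (ii < 0 || ii >= H) continue;
            double* d = dst0 + (std::size_t)B * (ii + (std::size_t)H * jj);
            const double* s = src + (std::size_t)B * i;
            for (int b = 0; b < B; ++b) d[b] += s[b];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
List conv2d_fwd_cpp(NumericVector x, IntegerVector dims,
                    const arma::mat& W, const arma::vec& b,
                    int kernel, int pad, bool keep_cols) {
  const int B = dims[0], H = dims[1], Wd = dims[2], C = dims[3];
  const int n = B * H * Wd;
  const int OC = W.n_cols;
  arma::mat* cols = new arma::mat(n, (std::size_t)kernel * kernel * C);
  im2col(REAL(x), B, H, Wd, C, kernel, pad, *cols);
  NumericVector res(Rcpp::no_init((std::size_t)n * OC));
  arma::mat out(REAL(res), n, OC, false, true);   // write GEMM output in place
  out = (*cols) * W;
  out.each_row() += b.t();
  res.attr("dim") = IntegerVector::create(B, H, Wd, OC);
  if (keep_cols) {
    XPtr<arma::mat> p(cols, true);
    return List::create(_["out"] = res, _["cols"] = p);
  }
  delete cols;
  return List::create(_["out"] = res);
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(SEXP cols_ptr, IntegerVector dims,
                    const arma::mat& W, NumericVector dy,
                    int kernel, int pad) {
  const int B = dims[0], H = dims[1], Wd = dims[2], C = dims[3];
  const int n = B * H * Wd;
  const int OC = W.n_cols;
  XPtr<arma::mat> cols(cols_ptr);
  const arma::mat dm(REAL(dy), n, OC, false, true);
  arma::mat dW = cols->t() * dm;
  arma::vec db = arma::sum(dm, 0).t();
  arma::mat dcols = dm * W.t();
  NumericVector dx((std::size_t)n * C);
  col2im(dcols, B, H, Wd, C, kernel, pad, REAL(dx));
  dx.attr("dim") = IntegerVector::create(B, H, Wd, C);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// fused batch-norm forward: y = x * scale[ch] + shift[ch], x is (n, C)
// [[Rcpp::export(name = ".scale_shift_cpp")]]
NumericVector scale_shift_cpp(NumericVector x, int C,
                              const arma::vec& scale, const arma::vec& shift) {
  const std::size_t n = (std::size_t)x.size() / C;
  NumericVector y(x.size());
  const double* xi = REAL(x);
  double* yo = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double sc = scale[c], sh = shift[c];
    const double* xs = xi + n * c;
    double* ys = yo + n * c;
    for (std::size_t r = 0; r < n; ++r) ys[r] = xs[r] * sc + sh;
  }
  return y;
}
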