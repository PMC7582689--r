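// im2col / col2im kernels for 2-D convolution on (H, W, C) arrays.
// Layout: x is an R array dim c(H, W, C); columns of the unrolled matrix
// enumerate output positions in column-major (ho fastest) order; rows
// enumerate (kh, kw, c) with kh fastest.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h >= 0 && h < H && w >= 0 && w < W)
              dst[kh + k * (kw + k * c)] = x(h, w, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h >= 0 && h < H && w >= 0 && w < W)
              x(h, w, c) += src[kh + k * (kw + k * c)];
          }
        }
      }
    }
  }
  return x;
}

// Full convolution forward: y = W^T cols + b. Returns y and the unrolled
// column matrix (cached for the backward pass).
// [[Rcpp::export]]
List cpp_conv_fw(const arma::cube& x, const arma::mat& W,
                 const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  arma::mat cols = cpp_im2col(x, k, stride, pad);
  arma::mat ym = cols.t() * W;            // (HoWo) x cout
  ym.each_row() += b.t();
  // (HoWo) x cout column-major == (Ho, Wo, cout) cube layout
  arma::cube y(ym.memptr(), Ho, Wo, W.n_cols);
  return List::create(_["y"] = y, _["cols"] = cols);
}

// Convolution backward: given cached cols and dy, return dx, dW, db.
// [[Rcpp::export]]
List cpp_conv_bw(const arma::mat& cols, const arma::mat& W,
                 const arma::cube& dy, int H, int Wd, int C,
                 int k, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const arma::mat dym(const_cast<double*>(dy.memptr()), Ho * Wo, Cout,
                      false, true);       // view of cube memory
  arma::mat dW = cols * dym;              // (kkC) x cout
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dcols = W * dym.t();          // (kkC) x (HoWo)
  arma::cube dx = cpp_col2im(dcols, H, Wd, C, k, stride, pad);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Per-channel spatial normalization with learned scale/shift.
// [[Rcpp::export]]
List cpp_chnorm_fw(const arma::cube& x, const arma::vec& gamma,
                   const arma::vec& beta, double eps) {
  const int C = x.n_slices;
  arma::cube y(x.n_rows, x.n_cols, C), xhat(x.n_rows, x.n_cols, C);
  arma::vec istd(C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    double mu = arma::accu(s) / s.n_elem;
    arma::mat ctr = s - mu;
    double v = arma::accu(ctr % ctr) / s.n_elem;
    double is = 1.0 / std::sqrt(v + eps);
    istd(c) = is;
    xhat.slice(c) = ctr * is;
    y.slice(c) = xhat.slice(c) * gamma(c) + beta(c);
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_chnorm_bw(const arma::cube& xhat, const arma::vec& istd,
                   const arma::vec& gamma, const arma::cube& dy) {
  const int C = dy.n_slices;
  arma::cube dx(dy.n_rows, dy.n_cols, C);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& g = dy.slice(c);
    const arma::mat& xh = xhat.slice(c);
    const double n = g.n_elem;
    dgamma(c) = arma::accu(g % xh);
    dbeta(c) = arma::accu(g);
    double m1 = dbeta(c) / n;
    double m2 = dgamma(c) / n;
    dx.slice(c) = (g - m1 - xh * m2) * (gamma(c) * istd(c));
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Non-overlapping average pooling, kernel = stride = k.
// [[Rcpp::export]]
arma::cube cpp_avgpool(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / k, Wo = W / k;
  arma::cube y(Ho, Wo, C, arma::fill::zeros);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0.0;
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            s += x(ho * k + kh, wo * k + kw, c);
        y(ho, wo, c) = s * inv;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_backward(const arma::cube& dy, int k) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(Ho * k, Wo * k, C, arma::fill::zeros);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dy(ho, wo, c) * inv;
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            dx(ho * k + kh, wo * k + kw, c) = g;
      }
  return dx;
}
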