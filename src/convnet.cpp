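// im2col/col2im convolution kernels backing the residual classifier.
// Tensors are R arrays in column-major order with dims (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// col matrix: (Ho*Wo) x (kh*kw*Cin), col(ho + Ho*wo, i + kh*(j + kw*c))
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   arma::mat& col) {
  const int Ho = out_size(H, kh, pad, stride);
  const int Wo = out_size(W, kw, pad, stride);
  col.zeros(Ho * (arma::uword)Wo, kh * (arma::uword)kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const arma::uword q = i + kh * (j + (arma::uword)kw * c);
        double* colq = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* xcw = xc + (size_t)wsrc * H;
          double* dst = colq + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride - pad + i;
            if (hsrc >= 0 && hsrc < H) dst[ho] = xcw[hsrc];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int pad, int stride,
                   double* x) {
  const int Ho = out_size(H, kh, pad, stride);
  const int Wo = out_size(W, kw, pad, stride);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const arma::uword q = i + kh * (j + (arma::uword)kw * c);
        const double* colq = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          double* xcw = xc + (size_t)wsrc * H;
          const double* src = colq + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride - pad + i;
            if (hsrc >= 0 && hsrc < H) xcw[hsrc] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv_fwd: channel mismatch");
  const int Ho = out_size(H, kh, pad, stride), Wo = out_size(W, kw, pad, stride);
  NumericVector y(Ho * (R_xlen_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wmat(w.begin(), kh * (arma::uword)kw * C, Cout, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, stride, col);
    arma::mat yn(y.begin() + (size_t)n * Ho * Wo * Cout,
                 Ho * (arma::uword)Wo, Cout, false, true);
    yn = col * wmat;
    for (int co = 0; co < Cout; ++co) yn.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_size(H, kh, pad, stride), Wo = out_size(W, kw, pad, stride);
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat wmat(w.begin(), kh * (arma::uword)kw * C, Cout, false, true);
  arma::mat dwmat(dw.begin(), kh * (arma::uword)kw * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col, dcol;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, stride, col);
    arma::mat dyn(dy.begin() + (size_t)n * Ho * Wo * Cout,
                  Ho * (arma::uword)Wo, Cout, false, true);
    dwmat += col.t() * dyn;
    dbv += arma::sum(dyn, 0).t();
    dcol = dyn * wmat.t();
    col2im(dcol, H, W, C, kh, kw, pad, stride,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
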