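// Minimal 2D convolution kernels (im2col) for the residual backbone.
// Layouts (column-major R arrays):
//   x:    (H, W, Cin, N)
//   w:    (kh, kw, Cin, Cout)
//   out:  (Ho, Wo, Cout, N)
// Patch rows are ordered dh + kh*(dw + kw*c), matching w's memory layout, so
// the kernel tensor reshapes directly to a (kh*kw*Cin) x Cout matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, arma::mat& cols) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  cols.zeros(kh * kw * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int row = dh + kh * (dw + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int wsrc = j * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int hsrc = i * stride - pad + dh;
            if (hsrc < 0 || hsrc >= H) continue;
            cols(row, i + Ho * j) = xc[hsrc + (size_t)wsrc * H];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad, double* dx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int row = dh + kh * (dw + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int wsrc = j * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int hsrc = i * stride - pad + dh;
            if (hsrc < 0 || hsrc >= H) continue;
            xc[hsrc + (size_t)wsrc * H] += cols(row, i + Ho * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d_fwd: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::rowvec b(const_cast<double*>(bias.begin()), Cout, false, true);

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, stride, pad, cols);
    arma::mat o = cols.t() * Wm;       // (Ho*Wo) x Cout
    o.each_row() += b;
    std::copy(o.begin(), o.end(), out.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, stride, pad, cols);
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)n * Ho * Wo * Cout,
                Ho * Wo, Cout, false, true);
    dWm += cols * G;
    dbv += arma::sum(G, 0).t();
    arma::mat dcols = Wm * G.t();      // (kh*kw*Cin) x (Ho*Wo)
    col2im(dcols, H, W, Cin, kh, kw, stride, pad,
           dx.begin() + (size_t)n * H * W * Cin);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
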