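// Low-level kernels for the CPU compute engine: 2-D convolution via
// im2col + GEMM, and bilinear resampling with half-pixel centers.
// Tensor layout everywhere: x[h, w, c, n] column-major (R array order),
// weights w[kh, kw, cin, cout]. im2col row index r = ki + kh*(kj + kw*ci)
// matches the flat layout of the weight array, so the kernel matrix is a
// zero-copy view.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int oh, int ow, arma::mat& col) {
  // col: (kh*kw*C) x (oh*ow), zero-filled by caller
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int j = 0; j < ow; ++j) {
          int wsrc = j * stride - pad + kj * dil;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* xcol = xc + (size_t)H * wsrc;
          double* cdst = col.colptr(0) + (size_t)col.n_rows * (size_t)oh * j + r;
          for (int i = 0; i < oh; ++i) {
            int hsrc = i * stride - pad + ki * dil;
            if (hsrc < 0 || hsrc >= H) continue;
            cdst[(size_t)col.n_rows * i] = xcol[hsrc];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int oh, int ow, double* x) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int j = 0; j < ow; ++j) {
          int wsrc = j * stride - pad + kj * dil;
          if (wsrc < 0 || wsrc >= W) continue;
          double* xcol = xc + (size_t)H * wsrc;
          const double* csrc = col.colptr(0) + (size_t)col.n_rows * (size_t)oh * j + r;
          for (int i = 0; i < oh; ++i) {
            int hsrc = i * stride - pad + ki * dil;
            if (hsrc < 0 || hsrc >= H) continue;
            xcol[hsrc] += csrc[(size_t)col.n_rows * i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  int oh = out_dim(H, kh, stride, pad, dil), ow = out_dim(W, kw, stride, pad, dil);
  if (oh < 1 || ow < 1) stop("conv2d: output would be empty");
  int K = kh * kw * Cin, P = oh * ow;

  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)P * Cout * N));
  y.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pad, dil, oh, ow, col);
    arma::mat Y(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    Y = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                        int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int oh = out_dim(H, kh, stride, pad, dil), ow = out_dim(W, kw, stride, pad, dil);
  int K = kh * kw * Cin, P = oh * ow;

  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xd;
  NumericVector dw(Rf_allocVector(REALSXP, w.size()));
  std::fill(dw.begin(), dw.end(), 0.0);
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat col(K, P), dcol(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)P * Cout * n,
                 P, Cout, false, true);
    col.zeros();
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pad, dil, oh, ow, col);
    dWm += col * dY;
    dcol = Wm * dY.t();
    col2im(dcol, H, W, C, kh, kw, stride, pad, dil, oh, ow,
           dx.begin() + (size_t)H * W * C * n);
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear resize, half-pixel sampling (align_corners = FALSE), edge clamp.
// [[Rcpp::export]]
NumericVector nn_bilinear(NumericVector x, int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)oh * ow * C * N));
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);

  std::vector<int> h0(oh), h1(oh); std::vector<double> hw(oh);
  std::vector<int> w0(ow), w1(ow); std::vector<double> ww(ow);
  double sh = (double)H / oh, sw = (double)W / ow;
  for (int i = 0; i < oh; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s); h1[i] = std::min(h0[i] + 1, H - 1); hw[i] = s - h0[i];
  }
  for (int j = 0; j < ow; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s); w1[j] = std::min(w0[j] + 1, W - 1); ww[j] = s - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (size_t)H * W * cn;
    double* yp = y.begin() + (size_t)oh * ow * cn;
    for (int j = 0; j < ow; ++j) {
      const double* c0 = xp + (size_t)H * w0[j];
      const double* c1 = xp + (size_t)H * w1[j];
      double* yc = yp + (size_t)oh * j;
      double b = ww[j];
      for (int i = 0; i < oh; ++i) {
        double a = hw[i];
        double top = (1 - b) * c0[h0[i]] + b * c1[h0[i]];
        double bot = (1 - b) * c0[h1[i]] + b * c1[h1[i]];
        yc[i] = (1 - a) * top + a * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_bilinear_backward(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int oh = yd[0], ow = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);

  std::vector<int> h0(oh), h1(oh); std::vector<double> hw(oh);
  std::vector<int> w0(ow), w1(ow); std::vector<double> ww(ow);
  double sh = (double)H / oh, sw = (double)W / ow;
  for (int i = 0; i < oh; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s); h1[i] = std::min(h0[i] + 1, H - 1); hw[i] = s - h0[i];
  }
  for (int j = 0; j < ow; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s); w1[j] = std::min(w0[j] + 1, W - 1); ww[j] = s - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    double* xp = dx.begin() + (size_t)H * W * cn;
    const double* yp = dy.begin() + (size_t)oh * ow * cn;
    for (int j = 0; j < ow; ++j) {
      double* c0 = xp + (size_t)H * w0[j];
      double* c1 = xp + (size_t)H * w1[j];
      const double* yc = yp + (size_t)oh * j;
      double b = ww[j];
      for (int i = 0; i < oh; ++i) {
        double a = hw[i], g = yc[i];
        c0[h0[i]] += (1 - a) * (1 - b) * g;
        c1[h0[i]] += (1 - a) * b * g;
        c0[h1[i]] += a * (1 - b) * g;
        c1[h1[i]] += a * b * g;
      }
    }
  }
  return dx;
}

// y = x * a[c] + b[c], per-channel affine over [H,W,C,N].
// [[Rcpp::export]]
NumericVector nn_chan_affine(NumericVector x, NumericVector a,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int C = xd[2], N = xd[3];
  size_t plane = (size_t)xd[0] * xd[1];
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double ac = a[c], bc = b[c];
      size_t off = plane * ((size_t)C * n + c);
      for (size_t i = 0; i < plane; ++i) yp[off + i] = xp[off + i] * ac + bc;
    }
  return y;
}

// Per-channel sum and sum of squares in one pass.
// [[Rcpp::export]]
List nn_chan_sums(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[2], N = xd[3];
  size_t plane = (size_t)xd[0] * xd[1];
  NumericVector s(C), s2(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double acc = 0, acc2 = 0;
      size_t off = plane * ((size_t)C * n + c);
      for (size_t i = 0; i < plane; ++i) {
        double v = xp[off + i];
        acc += v; acc2 += v * v;
      }
      s[c] += acc; s2[c] += acc2;
    }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// Per-channel sum of x*y (for batch-norm gamma gradients).
// [[Rcpp::export]]
NumericVector nn_chan_dot(NumericVector x, NumericVector y) {
  IntegerVector xd = x.attr("dim");
  int C = xd[2], N = xd[3];
  size_t plane = (size_t)xd[0] * xd[1];
  NumericVector s(C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double acc = 0;
      size_t off = plane * ((size_t)C * n + c);
      for (size_t i = 0; i < plane; ++i) acc += xp[off + i] * yp[off + i];
      s[c] += acc;
    }
  return s;
}

// dx = (dy - mdy[c] - xhat * mdyxh[c]) * gs[c]  (batch-norm training grad)
// [[Rcpp::export]]
NumericVector nn_bn_bwd(NumericVector dy, NumericVector xhat,
                        NumericVector gs, NumericVector mdy,
                        NumericVector mdyxh) {
  IntegerVector xd = dy.attr("dim");
  int C = xd[2], N = xd[3];
  size_t plane = (size_t)xd[0] * xd[1];
  NumericVector dx(Rf_allocVector(REALSXP, dy.size()));
  dx.attr("dim") = xd;
  const double* dyp = dy.begin();
  const double* xhp = xhat.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double g = gs[c], m1 = mdy[c], m2 = mdyxh[c];
      size_t off = plane * ((size_t)C * n + c);
      for (size_t i = 0; i < plane; ++i)
        dxp[off + i] = (dyp[off + i] - m1 - xhp[off + i] * m2) * g;
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector dy, NumericVector x) {
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  dx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? dp[i] : 0;
  return dx;
}
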