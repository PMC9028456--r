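// Numerical kernels for the network engine: im2col convolution (forward and
// backward), max pooling, and bilinear sampling under scale+shift affine
// transforms (the STN sampler) plus a general 2x3 affine warp used for image
// resizing and the synthetic renderer's viewpoint shear.
//
// Array layout convention (column-major, matching R): feature maps are
// [H, W, C, N]; convolution weights are [kh, kw, Cin, Cout].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& M) {
  // M: (kh*kw*C) x (Ho*Wo); column index wo*Ho + ho; row index i + kh*(j + kw*c)
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * stride - pad + j;
          const bool wok = (win >= 0 && win < W);
          double* Mcol = M.memptr() + (size_t)M.n_rows * (size_t)(wo * Ho) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * stride - pad + i;
            double v = 0.0;
            if (wok && hin >= 0 && hin < H)
              v = x[(size_t)hin + (size_t)H * (win + (size_t)W * c)];
            Mcol[(size_t)ho * M.n_rows] = v;
          }
        }
      }
    }
  }
}

static inline void col2im_accum(const arma::mat& dM, double* dx,
                                int H, int W, int C,
                                int kh, int kw, int stride, int pad,
                                int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * stride - pad + j;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * stride - pad + i;
            if (hin < 0 || hin >= H) continue;
            dx[(size_t)hin + (size_t)H * (win + (size_t)W * c)] +=
              dM(r, wo * Ho + ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = kh * kw * Cin;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bb(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat M(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, M);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    Y = M.t() * Wm;
    Y.each_row() += bb;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat M(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, M);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    dWm += M * dY;
    db += arma::sum(dY, 0);
    arma::mat dM = Wm * dY.t();
    col2im_accum(dM, dx.begin() + (size_t)H * W * C * n, H, W, C,
                 kh, kw, stride, pad, Ho, Wo);
  }
  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = wd;
  NumericVector dbv(db.begin(), db.end());
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int j = 0; j < k; ++j) {
            const int win = wo * stride - pad + j;
            if (win < 0 || win >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hin = ho * stride - pad + i;
              if (hin < 0 || hin >= H) continue;
              const size_t p = (size_t)hin + (size_t)H * (win + (size_t)W * c);
              if (xs[p] > best) { best = xs[p]; besti = p; }
            }
          }
          const size_t oo = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          y[oo] = best;
          idx[oo] = (int)((size_t)H * W * C * n + besti);
          ++o;
        }
      }
    }
  }
  (void)o;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= (size_t)xdim[i];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Normalized coordinate of output index i among n samples, align-corners.
static inline double ncoord(int i, int n) {
  return (n > 1) ? (-1.0 + 2.0 * i / (n - 1.0)) : 0.0;
}

// Bilinear sampling of x[H,W,C,N] under per-image scale+shift affine
// theta[4,N] = (sx, sy, tx, ty): source coords xs = sx*xo + tx, ys = sy*yo + ty
// with xo, yo in [-1,1] (align-corners); zero padding outside the source.
// [[Rcpp::export]]
NumericVector grid_sample_fwd_cpp(NumericVector x, NumericMatrix theta,
                                  int outH, int outW) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (theta.ncol() != N) stop("grid_sample: theta must be 4 x N");
  NumericVector y((size_t)outH * outW * C * N);
  y.attr("dim") = IntegerVector::create(outH, outW, C, N);
  for (int n = 0; n < N; ++n) {
    const double sx = theta(0, n), sy = theta(1, n);
    const double tx = theta(2, n), ty = theta(3, n);
    const double* xs0 = x.begin() + (size_t)H * W * C * n;
    for (int wo = 0; wo < outW; ++wo) {
      const double xo = ncoord(wo, outW);
      const double u = (sx * xo + tx + 1.0) * (W - 1) / 2.0;
      const int u0 = (int)std::floor(u);
      const double au = u - u0;
      for (int ho = 0; ho < outH; ++ho) {
        const double yo = ncoord(ho, outH);
        const double v = (sy * yo + ty + 1.0) * (H - 1) / 2.0;
        const int v0 = (int)std::floor(v);
        const double av = v - v0;
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int dj = 0; dj < 2; ++dj) {
            const int uu = u0 + dj;
            if (uu < 0 || uu >= W) continue;
            const double wu = dj ? au : (1.0 - au);
            for (int di = 0; di < 2; ++di) {
              const int vv = v0 + di;
              if (vv < 0 || vv >= H) continue;
              const double wv = di ? av : (1.0 - av);
              acc += wu * wv * xs0[(size_t)vv + (size_t)H * (uu + (size_t)W * c)];
            }
          }
          y[(size_t)ho + (size_t)outH * (wo + (size_t)outW * (c + (size_t)C * n))] = acc;
        }
      }
    }
  }
  return y;
}

// Backward of grid_sample_fwd_cpp: gradients w.r.t. the input map and the
// four affine parameters of each image.
// [[Rcpp::export]]
List grid_sample_bwd_cpp(NumericVector x, NumericMatrix theta, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int outH = yd[0], outW = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericMatrix dtheta(4, N);
  for (int n = 0; n < N; ++n) {
    const double sx = theta(0, n), sy = theta(1, n);
    const double tx = theta(2, n), ty = theta(3, n);
    const double* xs0 = x.begin() + (size_t)H * W * C * n;
    double* dx0 = dx.begin() + (size_t)H * W * C * n;
    for (int wo = 0; wo < outW; ++wo) {
      const double xo = ncoord(wo, outW);
      const double u = (sx * xo + tx + 1.0) * (W - 1) / 2.0;
      const int u0 = (int)std::floor(u);
      const double au = u - u0;
      for (int ho = 0; ho < outH; ++ho) {
        const double yo = ncoord(ho, outH);
        const double v = (sy * yo + ty + 1.0) * (H - 1) / 2.0;
        const int v0 = (int)std::floor(v);
        const double av = v - v0;
        double dLdu = 0.0, dLdv = 0.0;
        for (int c = 0; c < C; ++c) {
          const double g = dy[(size_t)ho + (size_t)outH *
                              (wo + (size_t)outW * (c + (size_t)C * n))];
          if (g == 0.0) continue;
          for (int dj = 0; dj < 2; ++dj) {
            const int uu = u0 + dj;
            if (uu < 0 || uu >= W) continue;
            const double wu = dj ? au : (1.0 - au);
            const double su = dj ? 1.0 : -1.0;   // d wu / du
            for (int di = 0; di < 2; ++di) {
              const int vv = v0 + di;
              if (vv < 0 || vv >= H) continue;
              const double wv = di ? av : (1.0 - av);
              const double sv = di ? 1.0 : -1.0; // d wv / dv
              const size_t p = (size_t)vv + (size_t)H * (uu + (size_t)W * c);
              dx0[p] += g * wu * wv;
              dLdu += g * su * wv * xs0[p];
              dLdv += g * wu * sv * xs0[p];
            }
          }
        }
        const double dudxs = (W - 1) / 2.0, dvdys = (H - 1) / 2.0;
        dtheta(0, n) += dLdu * dudxs * xo;  // d/dsx
        dtheta(1, n) += dLdv * dvdys * yo;  // d/dsy
        dtheta(2, n) += dLdu * dudxs;       // d/dtx
        dtheta(3, n) += dLdv * dvdys;       // d/dty
      }
    }
  }
  return List::create(_["dx"] = dx, _["dtheta"] = dtheta);
}

// General forward-only 2x3 affine warp (used for resizing and the synthetic
// renderer's viewpoint shear): source coords xs = a11*xo + a12*yo + a13,
// ys = a21*xo + a22*yo + a23 in [-1,1] normalized align-corners coordinates.
// A is 2x3, shared by all images in the stack; padding replicates the border
// when pad_border is true, else zero.
// [[Rcpp::export]]
NumericVector affine_warp_cpp(NumericVector x, NumericMatrix A,
                              int outH, int outW, bool pad_border) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)outH * outW * C * N);
  y.attr("dim") = IntegerVector::create(outH, outW, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xs0 = x.begin() + (size_t)H * W * C * n;
    for (int wo = 0; wo < outW; ++wo) {
      const double xo = ncoord(wo, outW);
      for (int ho = 0; ho < outH; ++ho) {
        const double yo = ncoord(ho, outH);
        const double xsn = A(0, 0) * xo + A(0, 1) * yo + A(0, 2);
        const double ysn = A(1, 0) * xo + A(1, 1) * yo + A(1, 2);
        const double u = (xsn + 1.0) * (W - 1) / 2.0;
        const double v = (ysn + 1.0) * (H - 1) / 2.0;
        const int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
        const double au = u - u0, av = v - v0;
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int dj = 0; dj < 2; ++dj) {
            int uu = u0 + dj;
            double wu = dj ? au : (1.0 - au);
            for (int di = 0; di < 2; ++di) {
              int vv = v0 + di;
              double wv = di ? av : (1.0 - av);
              int ucl = uu, vcl = vv;
              if (pad_border) {
                ucl = std::min(std::max(ucl, 0), W - 1);
                vcl = std::min(std::max(vcl, 0), H - 1);
              } else if (uu < 0 || uu >= W || vv < 0 || vv >= H) {
                continue;
              }
              acc += wu * wv * xs0[(size_t)vcl + (size_t)H * (ucl + (size_t)W * c)];
            }
          }
          y[(size_t)ho + (size_t)outH * (wo + (size_t)outW * (c + (size_t)C * n))] = acc;
        }
      }
    }
  }
  return y;
}
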