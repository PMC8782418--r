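// Low-level numerical kernels for the framelet GAN:
//  - 2D convolution forward/backward (im2col + GEMM), zero padding, any stride
//  - batched orthonormal 2D Haar analysis/synthesis
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix for one sample.
// K is (k*k*Cin) x (Ho*Wo); column j corresponds to output site
// (ho = j %% Ho, wo = j / Ho); row r = kh + k*kw + k*k*c.
static void im2col(const double* x, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& K) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int j = ho + Ho * wo;
      double* col = K.colptr(j);
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w = wo * stride - pad + kw;
          const bool win = (w >= 0 && w < W);
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh;
            const int r = kh + k * kw + k * k * c;
            col[r] = (win && h >= 0 && h < H) ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back onto the (padded) input grid.
static void col2im(const arma::mat& K, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int j = ho + Ho * wo;
      const double* col = K.colptr(j);
      for (int c = 0; c < Cin; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += col[kh + k * kw + k * k * c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (k, k, Cin, Cout)");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("only square kernels are supported");
  if (Cin != C) stop("input channels do not match the kernel");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("input is too small for this kernel/stride");

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat K((size_t)k * k * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, K);
    arma::mat Y(out.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    Y = K.t() * Wm;
    Y.each_row() += bv.t();
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad, bool need_dx, bool need_dw) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho, Wo, Cdy, Ndy;
  get_dims4(dy, Ho, Wo, Cdy, Ndy);
  if (Cdy != Cout || Ndy != N) stop("gradient shape does not match the layer");

  NumericVector dx, dw;
  NumericVector db(Cout);
  arma::mat dWm;
  if (need_dw) {
    dw = NumericVector((size_t)k * k * Cin * Cout);
    dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
    dWm = arma::mat(dw.begin(), (size_t)k * k * Cin, Cout, false, true);
  }
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  arma::mat K((size_t)k * k * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                       (size_t)Ho * Wo, Cout, false, true);
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dY.col(c));
    if (need_dw) {
      const double* xn = x.begin() + (size_t)H * W * C * n;
      im2col(xn, H, W, C, k, stride, pad, Ho, Wo, K);
      dWm += K * dY;
    }
    if (need_dx) {
      arma::mat dK = Wm * dY.t();
      col2im(dK, H, W, C, k, stride, pad, Ho, Wo,
             dx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Orthonormal 2D Haar analysis on each channel of each sample.
// Input (H, W, C, N), H and W even; output (H/2, W/2, 4C, N) with the
// channel blocks ordered LL | LH | HL | HH (LH = detail along width,
// HL = detail along height).  Every filter tap is +/- 1/2, so the transform
// is orthogonal: synthesis (and the gradient) is its transpose.
// [[Rcpp::export(name = ".haarForward")]]
NumericVector haar_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("Haar analysis requires even height and width");
  const int h2 = H / 2, w2 = W / 2;
  NumericVector out((size_t)h2 * w2 * 4 * C * N);
  out.attr("dim") = IntegerVector::create(h2, w2, 4 * C, N);
  const size_t planeIn = (size_t)H * W, planeOut = (size_t)h2 * w2;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + planeIn * (c + (size_t)C * n);
      double* ll = out.begin() + planeOut * (c + (size_t)4 * C * n);
      double* lh = ll + planeOut * C;
      double* hl = lh + planeOut * C;
      double* hh = hl + planeOut * C;
      for (int j = 0; j < w2; ++j) {
        for (int i = 0; i < h2; ++i) {
          const double a = xc[2 * i     + (size_t)H * (2 * j)];
          const double b = xc[2 * i     + (size_t)H * (2 * j + 1)];
          const double cc = xc[2 * i + 1 + (size_t)H * (2 * j)];
          const double d = xc[2 * i + 1 + (size_t)H * (2 * j + 1)];
          const size_t o = i + (size_t)h2 * j;
          ll[o] = 0.5 * ( a + b + cc + d);
          lh[o] = 0.5 * ( a - b + cc - d);
          hl[o] = 0.5 * ( a + b - cc - d);
          hh[o] = 0.5 * ( a - b - cc + d);
        }
      }
    }
  }
  return out;
}

// Inverse (synthesis): (H/2, W/2, 4C, N) -> (H, W, C, N).
// [[Rcpp::export(name = ".haarInverse")]]
NumericVector haar_inverse(NumericVector s) {
  int h2, w2, C4, N;
  get_dims4(s, h2, w2, C4, N);
  if (C4 % 4) stop("subband array must have 4*C channels");
  const int C = C4 / 4, H = 2 * h2, W = 2 * w2;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t planeIn = (size_t)h2 * w2, planeOut = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* ll = s.begin() + planeIn * (c + (size_t)C4 * n);
      const double* lh = ll + planeIn * C;
      const double* hl = lh + planeIn * C;
      const double* hh = hl + planeIn * C;
      double* xc = out.begin() + planeOut * (c + (size_t)C * n);
      for (int j = 0; j < w2; ++j) {
        for (int i = 0; i < h2; ++i) {
          const size_t o = i + (size_t)h2 * j;
          const double L = ll[o], Dw = lh[o], Dh = hl[o], Dd = hh[o];
          xc[2 * i     + (size_t)H * (2 * j)]     = 0.5 * (L + Dw + Dh + Dd);
          xc[2 * i     + (size_t)H * (2 * j + 1)] = 0.5 * (L - Dw + Dh - Dd);
          xc[2 * i + 1 + (size_t)H * (2 * j)]     = 0.5 * (L + Dw - Dh - Dd);
          xc[2 * i + 1 + (size_t)H * (2 * j + 1)] = 0.5 * (L - Dw - Dh + Dd);
        }
      }
    }
  }
  return out;
}

// Overlap-averaged reassembly with extended-precision accumulation, so
// that averaging k identical values returns the value bit-exactly.
// patches: list of p x p matrices; offsets: n x 2 integer matrix (0-based).
// [[Rcpp::export(name = ".overlapAverage")]]
NumericMatrix overlap_average(List patches, IntegerMatrix offsets,
                              int p, int H, int W) {
  std::vector<long double> acc((size_t)H * W, 0.0L);
  std::vector<int> cov((size_t)H * W, 0);
  const int n = patches.size();
  for (int i = 0; i < n; ++i) {
    NumericMatrix pm = patches[i];
    if (pm.nrow() != p || pm.ncol() != p) stop("patch %d has wrong shape", i + 1);
    const int r0 = offsets(i, 0), c0 = offsets(i, 1);
    if (r0 < 0 || c0 < 0 || r0 + p > H || c0 + p > W)
      stop("patch %d lies outside the image", i + 1);
    for (int c = 0; c < p; ++c) {
      for (int r = 0; r < p; ++r) {
        const size_t o = (size_t)(r0 + r) + (size_t)H * (c0 + c);
        acc[o] += (long double)pm(r, c);
        cov[o] += 1;
      }
    }
  }
  NumericMatrix out(H, W);
  for (size_t o = 0; o < (size_t)H * W; ++o) {
    if (cov[o] == 0) {
      const int col = (int)(o / H), row = (int)(o % H);
      stop("pixel (%d, %d) is covered by no patch", row, col);
    }
    out[o] = (double)(acc[o] / (long double)cov[o]);
  }
  return out;
}
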