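// Dense network primitives used by the trajectory-descriptor and scoring
// modules. Tensor layout everywhere: column-major R arrays dim c(W, H, C, N)
// (x fastest, then y, channel, sample); kernels dim c(kw, kh, Cin, Cout).
// Convolution is the deep-learning cross-correlation convention.

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dim4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() == 3) {
    d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2]; d[3] = 1;
  } else if (dm.size() == 4) {
    d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2]; d[3] = dm[3];
  } else if (dm.size() == 5) {
    // fold trailing dims: a (W,H,C,J,N) stack is treated as (W,H,C,J*N)
    d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2]; d[3] = dm[3] * dm[4];
  } else {
    stop("expected a 3- to 5-dimensional array");
  }
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// Column-wise min/max with 1-based argmin/argmax in a single pass.
// [[Rcpp::export]]
List col_minmax_cpp(NumericMatrix x) {
  int P = x.nrow(), M = x.ncol();
  NumericVector mins(M), maxs(M);
  IntegerVector jmin(M), jmax(M);
  for (int m = 0; m < M; ++m) {
    const double *c = &x(0, m);
    double lo = c[0], hi = c[0];
    int ilo = 0, ihi = 0;
    for (int p = 1; p < P; ++p) {
      if (c[p] < lo) { lo = c[p]; ilo = p; }
      if (c[p] > hi) { hi = c[p]; ihi = p; }
    }
    mins[m] = lo; maxs[m] = hi; jmin[m] = ilo + 1; jmax[m] = ihi + 1;
  }
  return List::create(_["min"] = mins, _["max"] = maxs,
                      _["jmin"] = jmin, _["jmax"] = jmax);
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather the im2col matrix (kw*kh*Cin x OW*OH) for one sample.
static void im2col(const double *x, int W, int H, int C,
                   int kw, int kh, int stride, int pad,
                   int OW, int OH, arma::mat &cols) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * W * H;
    for (int ky = 0; ky < kh; ++ky) {
      for (int kx = 0; kx < kw; ++kx) {
        int row = kx + kw * (ky + kh * c);
        for (int oy = 0; oy < OH; ++oy) {
          int iy = oy * stride - pad + ky;
          double *dst = cols.colptr(0) + row; // strided writes below
          if (iy < 0 || iy >= H) {
            for (int ox = 0; ox < OW; ++ox)
              cols(row, ox + OW * oy) = 0.0;
            continue;
          }
          for (int ox = 0; ox < OW; ++ox) {
            int ix = ox * stride - pad + kx;
            cols(row, ox + OW * oy) =
              (ix >= 0 && ix < W) ? xc[ix + W * iy] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add the im2col matrix back into a gradient image.
static void col2im(const arma::mat &cols, int W, int H, int C,
                   int kw, int kh, int stride, int pad,
                   int OW, int OH, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)c * W * H;
    for (int ky = 0; ky < kh; ++ky) {
      for (int kx = 0; kx < kw; ++kx) {
        int row = kx + kw * (ky + kh * c);
        for (int oy = 0; oy < OH; ++oy) {
          int iy = oy * stride - pad + ky;
          if (iy < 0 || iy >= H) continue;
          for (int ox = 0; ox < OW; ++ox) {
            int ix = ox * stride - pad + kx;
            if (ix < 0 || ix >= W)
              continue;
            xc[ix + W * iy] += cols(row, ox + OW * oy);
          }
        }
      }
    }
  }
}


// Transposed im2col for "same" stride-1 convolution on a single channel:
// cols(p, k) = img[p + o_k] with proper 2D zero bounds, columns ordered
// kx fastest. `flip` negates the offsets (used for gradient correlations).
static void im2colT1(const double *img, int W, int H, int k, bool flip,
                     arma::mat &cols) {
  int pad = (k - 1) / 2;
  for (int ky = 0; ky < k; ++ky) {
    for (int kx = 0; kx < k; ++kx) {
      int dx = kx - pad, dy = ky - pad;
      if (flip) { dx = -dx; dy = -dy; }
      double *dst = cols.colptr(kx + k * ky);
      for (int y = 0; y < H; ++y) {
        int sy = y + dy;
        double *row = dst + (size_t)W * y;
        if (sy < 0 || sy >= H) {
          std::memset(row, 0, W * sizeof(double));
          continue;
        }
        int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        if (x0 > 0) std::memset(row, 0, x0 * sizeof(double));
        if (x1 < W) std::memset(row + x1, 0, (W - x1) * sizeof(double));
        if (x1 > x0)
          std::memcpy(row + x0, img + x0 + dx + (size_t)W * sy,
                      (x1 - x0) * sizeof(double));
      }
    }
  }
}

// Scatter-add columns of M (P x k*k) back into a single-channel image:
// img[p + o_k] += M(p, k) with proper 2D bounds.
static void col2imT1(const arma::mat &M, int W, int H, int k, double *img) {
  int pad = (k - 1) / 2;
  for (int ky = 0; ky < k; ++ky) {
    int dy = ky - pad;
    for (int kx = 0; kx < k; ++kx) {
      int dx = kx - pad;
      const double *src = M.colptr(kx + k * ky);
      for (int y = 0; y < H; ++y) {
        int sy = y + dy;
        if (sy < 0 || sy >= H) continue;
        int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        double *dst = img + dx + (size_t)W * sy;
        for (int x = x0; x < x1; ++x) dst[x] += src[x + (size_t)W * y];
      }
    }
  }
}

// "Same" stride-1 convolution as a sum of shifted GEMMs: for each kernel
// offset (dx, dy) the contribution is a flat row-shifted matrix product
// Y.rows(r0, r1) += X.rows(r0+o, r1+o) * Wk with o = dx + W*dy, which lands
// in BLAS instead of scalar loops. The flat shift wraps horizontally at row
// edges (|dx| columns), so those few pixels are corrected scalar-wise after
// the GEMM. Exactly equivalent to the padded convolution.
static void conv_same_fwd(const double *x, const double *w, const double *b,
                          int W, int H, int C, int N, int k, int Cout,
                          double *y) {
  int pad = (k - 1) / 2;
  size_t P = (size_t)W * H;
  if (C == 1) {
    // single input channel: one fat GEMM per image on the gathered matrix
    arma::mat cols(P, (size_t)k * k);
    arma::mat Wm(const_cast<double *>(w), (size_t)k * k, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      im2colT1(x + n * P, W, H, k, false, cols);
      arma::mat Y(y + n * P * Cout, P, Cout, false, true);
      Y = cols * Wm;
      for (int co = 0; co < Cout; ++co)
        Y.col(co) += b[co];
    }
    return;
  }
  arma::mat Wk(C, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double *>(x) + n * P * C, P, C, false, true);
    arma::mat Y(y + n * P * Cout, P, Cout, false, true);
    for (int co = 0; co < Cout; ++co)
      Y.col(co).fill(b[co]);
    for (int ky = 0; ky < k; ++ky) {
      int dy = ky - pad;
      for (int kx = 0; kx < k; ++kx) {
        int dx = kx - pad;
        long o = dx + (long)W * dy;
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wk(ci, co) = w[kx + k * (ky + k * (ci + (size_t)C * co))];
        long r0 = std::max(0L, -o), r1 = (long)P - 1 - std::max(0L, o);
        if (r1 < r0) continue;
        {
          const int m = (int)(r1 - r0 + 1), nn = Cout, kk = C, ldx = (int)P;
          const double one = 1.0;
          F77_CALL(dgemm)("N", "N", &m, &nn, &kk, &one,
                          X.memptr() + r0 + o, &ldx, Wk.memptr(), &kk, &one,
                          Y.memptr() + r0, &ldx FCONE FCONE);
        }
        // undo horizontally wrapped contributions
        if (dx != 0) {
          int ox_lo = dx > 0 ? W - dx : 0;
          int ox_hi = dx > 0 ? W : -dx;
          for (int oy = 0; oy < H; ++oy) {
            for (int ox = ox_lo; ox < ox_hi; ++ox) {
              long p = ox + (long)W * oy;
              if (p < r0 || p > r1) continue;
              for (int co = 0; co < Cout; ++co) {
                double acc = 0.0;
                for (int ci = 0; ci < C; ++ci)
                  acc += X(p + o, ci) * Wk(ci, co);
                Y(p, co) -= acc;
              }
            }
          }
        }
      }
    }
  }
}

static void conv_same_bwd(const double *x, const double *w, const double *dy,
                          int W, int H, int C, int N, int k, int Cout,
                          bool need_dx, double *dxp, double *dwp, double *dbp) {
  int pad = (k - 1) / 2;
  size_t P = (size_t)W * H;
  if (C == 1) {
    // dW via the gathered input matrix, dX via one GEMM + scatter-add
    arma::mat cols(P, (size_t)k * k);
    arma::mat Wm(const_cast<double *>(w), (size_t)k * k, Cout, false, true);
    arma::mat dWm((size_t)k * k, Cout, arma::fill::zeros);
    arma::mat M;
    for (int n = 0; n < N; ++n) {
      arma::mat dY(const_cast<double *>(dy) + n * P * Cout, P, Cout, false, true);
      im2colT1(x + n * P, W, H, k, false, cols);
      dWm += cols.t() * dY;
      for (int co = 0; co < Cout; ++co)
        dbp[co] += arma::accu(dY.col(co));
      if (need_dx) {
        M = dY * Wm.t();                 // (P, k*k)
        col2imT1(M, W, H, k, dxp + n * P);
      }
    }
    std::copy(dWm.begin(), dWm.end(), dwp);
    return;
  }
  if (Cout == 1) {
    // correlate the (flipped-offset) gathered gradient with the input
    arma::mat cols(P, (size_t)k * k);
    arma::mat dWm(C, (size_t)k * k, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const double *dyn = dy + n * P;
      double acc = 0.0;
      for (size_t p = 0; p < P; ++p) acc += dyn[p];
      dbp[0] += acc;
      im2colT1(dyn, W, H, k, true, cols);
      arma::mat X(const_cast<double *>(x) + n * P * C, P, C, false, true);
      dWm += X.t() * cols;               // (C, k*k)
      if (need_dx) {
        arma::mat dX(dxp + n * P * C, P, C, false, true);
        // dX[:, ci] += cols * w_row(ci): w viewed as (k*k) per channel
        arma::vec wv((size_t)k * k);
        for (int ci = 0; ci < C; ++ci) {
          for (int kk_ = 0; kk_ < k * k; ++kk_) wv[kk_] = w[kk_ + k * k * ci];
          dX.col(ci) += cols * wv;
        }
      }
    }
    // scatter dWm(ci, k) into w layout (kx, ky, ci)
    for (int kk_ = 0; kk_ < k * k; ++kk_)
      for (int ci = 0; ci < C; ++ci)
        dwp[kk_ + k * k * ci] += dWm(ci, kk_);
    return;
  }
  arma::mat Wk(C, Cout), dWk(C, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double *>(x) + n * P * C, P, C, false, true);
    arma::mat dY(const_cast<double *>(dy) + n * P * Cout, P, Cout, false, true);
    arma::mat dX(dxp + n * P * C, P, C, false, true);
    for (int co = 0; co < Cout; ++co)
      dbp[co] += arma::accu(dY.col(co));
    for (int ky = 0; ky < k; ++ky) {
      int dy_ = ky - pad;
      for (int kx = 0; kx < k; ++kx) {
        int dx_ = kx - pad;
        long o = dx_ + (long)W * dy_;
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wk(ci, co) = w[kx + k * (ky + k * (ci + (size_t)C * co))];
        long r0 = std::max(0L, -o), r1 = (long)P - 1 - std::max(0L, o);
        if (r1 < r0) continue;
        {
          const int len = (int)(r1 - r0 + 1), ldx = (int)P, cc = C, co_ = Cout;
          const int ione = 1;
          const double one = 1.0, zero = 0.0;
          if (Cout == 1) {
            // dW = X^T dy and dX += dy w^T collapse to gemv / axpy
            F77_CALL(dgemv)("T", &len, &cc, &one, X.memptr() + r0 + o, &ldx,
                            dY.memptr() + r0, &ione, &zero, dWk.memptr(),
                            &ione FCONE);
            if (need_dx)
              for (int ci = 0; ci < C; ++ci) {
                double wv = Wk(ci, 0);
                F77_CALL(daxpy)(&len, &wv, dY.memptr() + r0, &ione,
                                dX.colptr(ci) + r0 + o, &ione);
              }
          } else {
            F77_CALL(dgemm)("T", "N", &cc, &co_, &len, &one,
                            X.memptr() + r0 + o, &ldx, dY.memptr() + r0, &ldx,
                            &zero, dWk.memptr(), &cc FCONE FCONE);
            if (need_dx)
              F77_CALL(dgemm)("N", "T", &len, &cc, &co_, &one,
                              dY.memptr() + r0, &ldx, Wk.memptr(), &cc, &one,
                              dX.memptr() + r0 + o, &ldx FCONE FCONE);
          }
        }
        if (dx_ != 0) {
          int ox_lo = dx_ > 0 ? W - dx_ : 0;
          int ox_hi = dx_ > 0 ? W : -dx_;
          for (int oy = 0; oy < H; ++oy) {
            for (int ox = ox_lo; ox < ox_hi; ++ox) {
              long p = ox + (long)W * oy;
              if (p < r0 || p > r1) continue;
              for (int co = 0; co < Cout; ++co) {
                double g = dY(p, co);
                for (int ci = 0; ci < C; ++ci) {
                  dWk(ci, co) -= X(p + o, ci) * g;
                  if (need_dx) dX(p + o, ci) -= Wk(ci, co) * g;
                }
              }
            }
          }
        }
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            dwp[kx + k * (ky + k * (ci + (size_t)C * co))] += dWk(ci, co);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  int dx4[4], dw4[4];
  get_dim4(x, dx4); get_dim4(w, dw4);
  int W = dx4[0], H = dx4[1], C = dx4[2], N = dx4[3];
  int kw = dw4[0], kh = dw4[1], Cin = dw4[2], Cout = dw4[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  if (b.size() != Cout) stop("conv2d: bias length != Cout");
  int OW = out_size(W, kw, stride, pad), OH = out_size(H, kh, stride, pad);
  if (OW <= 0 || OH <= 0) stop("conv2d: output size would be non-positive");

  NumericVector y((R_xlen_t)OW * OH * Cout * N);
  y.attr("dim") = IntegerVector::create(OW, OH, Cout, N);
  // shifted-GEMM path for stride-1 same-size convolutions
  if (stride == 1 && kw == kh && OW == W && OH == H) {
    conv_same_fwd(x.begin(), w.begin(), b.begin(), W, H, C, N, kw, Cout,
                  y.begin());
    return y;
  }
  arma::mat Wm(const_cast<double *>(w.begin()), kw * kh * Cin, Cout, false, true);
  arma::vec bv(const_cast<double *>(b.begin()), Cout, false, true);
  arma::mat cols(kw * kh * Cin, OW * OH);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * W * H * C, W, H, C, kw, kh, stride, pad, OW, OH, cols);
    arma::mat yn = cols.t() * Wm;            // (OW*OH, Cout)
    yn.each_row() += bv.t();
    std::copy(yn.begin(), yn.end(), y.begin() + (size_t)n * OW * OH * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx = true) {
  int dx4[4], dw4[4], dy4[4];
  get_dim4(x, dx4); get_dim4(w, dw4); get_dim4(dy, dy4);
  int W = dx4[0], H = dx4[1], C = dx4[2], N = dx4[3];
  int kw = dw4[0], kh = dw4[1], Cin = dw4[2], Cout = dw4[3];
  int OW = dy4[0], OH = dy4[1];
  if (dy4[2] != Cout || dy4[3] != N) stop("conv2d_bwd: dy shape mismatch");

  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = x.attr("dim");

  if (stride == 1 && kw == kh && OW == W && OH == H) {
    NumericVector dWr((R_xlen_t)kw * kh * Cin * Cout);
    dWr.attr("dim") = w.attr("dim");
    NumericVector db(Cout);
    conv_same_bwd(x.begin(), w.begin(), dy.begin(), W, H, C, N, kw, Cout,
                  need_dx, dx.begin(), dWr.begin(), db.begin());
    return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = db);
  }

  arma::mat Wm(const_cast<double *>(w.begin()), kw * kh * Cin, Cout, false, true);
  arma::mat dW(kw * kh * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(kw * kh * Cin, OW * OH);
  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double *>(dy.begin()) + (size_t)n * OW * OH * Cout,
                  OW * OH, Cout, false, true);
    im2col(x.begin() + (size_t)n * W * H * C, W, H, C, kw, kh, stride, pad, OW, OH, cols);
    dW += cols * dYn;
    db += arma::sum(dYn, 0).t();
    if (need_dx) {
      arma::mat dcols = Wm * dYn.t();        // (kkC, OW*OH)
      col2im(dcols, W, H, C, kw, kh, stride, pad, OW, OH,
             dx.begin() + (size_t)n * W * H * C);
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = w.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Batched separable-Gaussian clip renderer: centers cx, cy and confidences
// conf are (T, J, N); returns (W, H, T, J, N). Exactly
// conf * exp(-d^2 / (2 sigma^2)) per pixel; confidence below `thr` renders
// as all-zero (occluded joint).
// [[Rcpp::export]]
NumericVector render_clips_cpp(NumericVector cx, NumericVector cy,
                               NumericVector conf, int W, int H,
                               double sigma, double thr) {
  IntegerVector dm = cx.attr("dim");
  int T = dm[0], J = dm.size() > 1 ? dm[1] : 1, N = dm.size() > 2 ? dm[2] : 1;
  R_xlen_t nmaps = (R_xlen_t)T * J * N;
  NumericVector y((R_xlen_t)W * H * nmaps);
  y.attr("dim") = IntegerVector::create(W, H, T, J, N);
  std::vector<double> gx(W), gy(H);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (R_xlen_t m = 0; m < nmaps; ++m) {
    double c = conf[m];
    if (c < thr) continue;
    double mx = cx[m], my = cy[m];
    for (int i = 0; i < W; ++i) gx[i] = std::exp(-(i - mx) * (i - mx) * inv2s2);
    for (int j = 0; j < H; ++j) gy[j] = c * std::exp(-(j - my) * (j - my) * inv2s2);
    double *dst = y.begin() + (size_t)m * W * H;
    for (int j = 0; j < H; ++j) {
      double g = gy[j];
      for (int i = 0; i < W; ++i) dst[i + (size_t)W * j] = g * gx[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  int d4[4];
  get_dim4(x, d4);
  int W = d4[0], H = d4[1], C = d4[2], N = d4[3];
  int OW = out_size(W, k, stride, pad), OH = out_size(H, k, stride, pad);
  if (OW <= 0 || OH <= 0) stop("maxpool: output size would be non-positive");
  if (k == 2 && stride == 2 && pad == 0) {
    // specialized 2x2/2 pooling: branch-light pairwise max
    NumericVector y((R_xlen_t)OW * OH * C * N);
    y.attr("dim") = IntegerVector::create(OW, OH, C, N);
    IntegerVector idx(y.size());
    size_t p = 0;
    for (R_xlen_t img = 0; img < (R_xlen_t)C * N; ++img) {
      const double *xc = x.begin() + (size_t)img * W * H;
      size_t base = (size_t)img * W * H;
      for (int oy = 0; oy < OH; ++oy) {
        const double *r0 = xc + (size_t)W * (2 * oy);
        const double *r1 = r0 + W;
        for (int ox = 0; ox < OW; ++ox, ++p) {
          int i0 = 2 * ox;
          double v = r0[i0]; int bi = i0 + W * (2 * oy);
          if (r0[i0 + 1] > v) { v = r0[i0 + 1]; bi = i0 + 1 + W * (2 * oy); }
          if (r1[i0] > v) { v = r1[i0]; bi = i0 + W * (2 * oy + 1); }
          if (r1[i0 + 1] > v) { v = r1[i0 + 1]; bi = i0 + 1 + W * (2 * oy + 1); }
          y[p] = v;
          idx[p] = (int)(base + bi);
        }
      }
    }
    return List::create(_["y"] = y, _["idx"] = idx);
  }
  NumericVector y((R_xlen_t)OW * OH * C * N);
  y.attr("dim") = IntegerVector::create(OW, OH, C, N);
  IntegerVector idx(y.size()); // 0-based flat index into x of each argmax
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)(c + (size_t)n * C) * W * H;
      size_t base = (size_t)(c + (size_t)n * C) * W * H;
      for (int oy = 0; oy < OH; ++oy) {
        for (int ox = 0; ox < OW; ++ox, ++p) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            for (int kx = 0; kx < k; ++kx) {
              int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= W) continue;
              double v = xc[ix + W * iy];
              if (v > best) { best = v; bi = ix + W * iy; }
            }
          }
          // reorder: p runs ox fastest but we filled row-major over (ox,oy);
          // the flat output index is ox + OW*(oy + OH*(c + C*n)) == p by loop order
          y[p] = best;
          idx[p] = (int)(base + bi);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  size_t nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= xdim[i];
  NumericVector dx((R_xlen_t)nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Bilinear sampling with zeros padding. x: (W, H, N); gx, gy: (P, N) source
// points in 0-based pixel coordinates; returns y: (P, N). Neighbours falling
// outside the image contribute zero, so fully out-of-bounds points sample 0.
// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, NumericMatrix gx,
                               NumericMatrix gy) {
  int d4[4];
  get_dim4(x, d4);
  int W = d4[0], H = d4[1], N = d4[2] * d4[3];
  int P = gx.nrow();
  if (gx.ncol() != N || gy.nrow() != P || gy.ncol() != N)
    stop("bilinear: grid shape mismatch");
  NumericMatrix y(P, N);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * W * H;
    for (int p = 0; p < P; ++p) {
      double sx = gx(p, n), sy = gy(p, n);
      if (!R_finite(sx) || !R_finite(sy)) stop("bilinear: non-finite grid point");
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      double ax = sx - x0, ay = sy - y0;
      double v = 0.0;
      for (int dyy = 0; dyy <= 1; ++dyy) {
        int yy = y0 + dyy;
        if (yy < 0 || yy >= H) continue;
        double wy = dyy ? ay : 1.0 - ay;
        for (int dxx = 0; dxx <= 1; ++dxx) {
          int xx = x0 + dxx;
          if (xx < 0 || xx >= W) continue;
          double wx = dxx ? ax : 1.0 - ax;
          v += wx * wy * xn[xx + W * yy];
        }
      }
      y(p, n) = v;
    }
  }
  return y;
}

// [[Rcpp::export]]
List bilinear_bwd_cpp(NumericVector x, NumericMatrix gx, NumericMatrix gy,
                      NumericMatrix dy) {
  int d4[4];
  get_dim4(x, d4);
  int W = d4[0], H = d4[1], N = d4[2] * d4[3];
  int P = gx.nrow();
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericMatrix dgx(P, N), dgy(P, N);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * W * H;
    double *dxn = dx.begin() + (size_t)n * W * H;
    for (int p = 0; p < P; ++p) {
      double g = dy(p, n);
      if (g == 0.0) continue;
      double sx = gx(p, n), sy = gy(p, n);
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      double ax = sx - x0, ay = sy - y0;
      double ddx = 0.0, ddy = 0.0;
      for (int dyy = 0; dyy <= 1; ++dyy) {
        int yy = y0 + dyy;
        if (yy < 0 || yy >= H) continue;
        double wy = dyy ? ay : 1.0 - ay;
        double swy = dyy ? 1.0 : -1.0;
        for (int dxx = 0; dxx <= 1; ++dxx) {
          int xx = x0 + dxx;
          if (xx < 0 || xx >= W) continue;
          double wx = dxx ? ax : 1.0 - ax;
          double swx = dxx ? 1.0 : -1.0;
          double v = xn[xx + W * yy];
          dxn[xx + W * yy] += g * wx * wy;
          ddx += g * swx * wy * v;
          ddy += g * wx * swy * v;
        }
      }
      dgx(p, n) = ddx;
      dgy(p, n) = ddy;
    }
  }
  return List::create(_["dx"] = dx, _["dgx"] = dgx, _["dgy"] = dgy);
}
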