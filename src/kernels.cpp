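// Dense-array kernels for the segmentation engine.
//
// Layout conventions (column-major R arrays):
//   volumes / feature maps : dim = (X, Y, Z, C)
//   3D conv weights        : dim = (k, k, k, Cin, Cout)
//   slice-folded 2D maps   : dim = (X, Y, C, M)   (M = slices x batch)
//   2D depthwise weights   : dim = (kx, ky, C)
//
// Convolutions use zero padding of (k-1)/2 so stride-1 output matches the
// input grid and stride-2 output is ceil(dim/2).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outDim(int n, int k, int stride) {
  int p = (k - 1) / 2;
  return (n + 2 * p - k) / stride + 1;
}

// im2col for cubic kernels; col is (k^3*Ci) x (Xo*Yo*Zo)
static void im2col3(const double* x, int X, int Y, int Z, int Ci,
                    int k, int stride, arma::mat& col) {
  const int p = (k - 1) / 2;
  const int Xo = outDim(X, k, stride), Yo = outDim(Y, k, stride),
            Zo = outDim(Z, k, stride);
  col.zeros(k * k * k * Ci, (arma::uword)Xo * Yo * Zo);
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (size_t)X * Y * Z * ci;
    for (int l = 0; l < k; ++l) for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * l + k * k * k * ci;
        for (int zo = 0; zo < Zo; ++zo) {
          const int z = zo * stride + l - p;
          if (z < 0 || z >= Z) continue;
          for (int yo = 0; yo < Yo; ++yo) {
            const int y = yo * stride + j - p;
            if (y < 0 || y >= Y) continue;
            double* cc = col.colptr((arma::uword)Xo * (yo + (arma::uword)Yo * zo)) + r;
            const double* xr = xc + (size_t)X * (y + (size_t)Y * z);
            for (int xo = 0; xo < Xo; ++xo) {
              const int xx = xo * stride + i - p;
              if (xx >= 0 && xx < X) cc[(size_t)xo * col.n_rows] = xr[xx];
            }
          }
        }
      }
  }
}

static void col2im3(const arma::mat& col, int X, int Y, int Z, int Ci,
                    int k, int stride, double* dx) {
  const int p = (k - 1) / 2;
  const int Xo = outDim(X, k, stride), Yo = outDim(Y, k, stride),
            Zo = outDim(Z, k, stride);
  std::fill(dx, dx + (size_t)X * Y * Z * Ci, 0.0);
  for (int ci = 0; ci < Ci; ++ci) {
    double* xc = dx + (size_t)X * Y * Z * ci;
    for (int l = 0; l < k; ++l) for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * l + k * k * k * ci;
        for (int zo = 0; zo < Zo; ++zo) {
          const int z = zo * stride + l - p;
          if (z < 0 || z >= Z) continue;
          for (int yo = 0; yo < Yo; ++yo) {
            const int y = yo * stride + j - p;
            if (y < 0 || y >= Y) continue;
            const double* cc = col.colptr((arma::uword)Xo * (yo + (arma::uword)Yo * zo)) + r;
            double* xr = xc + (size_t)X * (y + (size_t)Y * z);
            for (int xo = 0; xo < Xo; ++xo) {
              const int xx = xo * stride + i - p;
              if (xx >= 0 && xx < X) xr[xx] += cc[(size_t)xo * col.n_rows];
            }
          }
        }
      }
  }
}

// stride-1 path: one GEMM per kernel tap on a shifted copy of the input,
// avoiding the k^3-fold im2col blow-up in memory traffic
static void shift_copy_f(const float* x, int X, int Y, int Z, int Ci,
                         int dx, int dy, int dz, float* xs) {
  for (int c = 0; c < Ci; ++c) {
    const float* xc = x + (size_t)X * Y * Z * c;
    float* sc = xs + (size_t)X * Y * Z * c;
    for (int z = 0; z < Z; ++z) {
      const int zz = z + dz;
      for (int y = 0; y < Y; ++y) {
        float* line = sc + (size_t)X * (y + (size_t)Y * z);
        const int yy = y + dy;
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y) {
          std::fill(line, line + X, 0.0f);
          continue;
        }
        const float* src = xc + (size_t)X * (yy + (size_t)Y * zz);
        const int lo = std::max(0, -dx), hi = std::min(X, X - dx);
        if (lo > 0) std::fill(line, line + lo, 0.0f);
        if (hi > lo) std::copy(src + lo + dx, src + hi + dx, line + lo);
        if (hi < X) std::fill(line + hi, line + X, 0.0f);
      }
    }
  }
}

static void shift_add_f(const float* g, int X, int Y, int Z, int Ci,
                        int dx, int dy, int dz, float* out) {
  for (int c = 0; c < Ci; ++c) {
    const float* gc = g + (size_t)X * Y * Z * c;
    float* oc = out + (size_t)X * Y * Z * c;
    for (int z = 0; z < Z; ++z) {
      const int zz = z + dz;
      if (zz < 0 || zz >= Z) continue;
      for (int y = 0; y < Y; ++y) {
        const int yy = y + dy;
        if (yy < 0 || yy >= Y) continue;
        const float* src = gc + (size_t)X * (y + (size_t)Y * z);
        float* dst = oc + (size_t)X * (yy + (size_t)Y * zz);
        const int lo = std::max(0, -dx), hi = std::min(X, X - dx);
        for (int i = lo; i < hi; ++i) dst[i + dx] += src[i];
      }
    }
  }
}

static void shift_copy(const double* x, int X, int Y, int Z, int Ci,
                       int dx, int dy, int dz, double* xs) {
  for (int c = 0; c < Ci; ++c) {
    const double* xc = x + (size_t)X * Y * Z * c;
    double* sc = xs + (size_t)X * Y * Z * c;
    for (int z = 0; z < Z; ++z) {
      const int zz = z + dz;
      for (int y = 0; y < Y; ++y) {
        double* line = sc + (size_t)X * (y + (size_t)Y * z);
        const int yy = y + dy;
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y) {
          std::fill(line, line + X, 0.0);
          continue;
        }
        const double* src = xc + (size_t)X * (yy + (size_t)Y * zz);
        const int lo = std::max(0, -dx), hi = std::min(X, X - dx);
        if (lo > 0) std::fill(line, line + lo, 0.0);
        if (hi > lo) std::copy(src + lo + dx, src + hi + dx, line + lo);
        if (hi < X) std::fill(line + hi, line + X, 0.0);
      }
    }
  }
}

static void shift_add(const double* g, int X, int Y, int Z, int Ci,
                      int dx, int dy, int dz, double* out) {
  for (int c = 0; c < Ci; ++c) {
    const double* gc = g + (size_t)X * Y * Z * c;
    double* oc = out + (size_t)X * Y * Z * c;
    for (int z = 0; z < Z; ++z) {
      const int zz = z + dz;
      if (zz < 0 || zz >= Z) continue;
      for (int y = 0; y < Y; ++y) {
        const int yy = y + dy;
        if (yy < 0 || yy >= Y) continue;
        const double* src = gc + (size_t)X * (y + (size_t)Y * z);
        double* dst = oc + (size_t)X * (yy + (size_t)Y * zz);
        const int lo = std::max(0, -dx), hi = std::min(X, X - dx);
        for (int i = lo; i < hi; ++i) dst[i + dx] += src[i];
      }
    }
  }
}

// forward accumulates in double (deployment-equivalence checks compare
// forward outputs); backward uses single precision, which gradients
// tolerate (mixed precision)
static NumericVector conv3s1_fwd(NumericVector x, NumericVector w) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int X = dx[0], Y = dx[1], Z = dx[2], Ci = dx[3];
  const int k = dw[0], Co = dw[4], p = (k - 1) / 2;
  const arma::uword V = (arma::uword)X * Y * Z;
  NumericVector res(V * Co);
  res.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  arma::mat ym(REAL(res), V, Co, false, true);
  arma::mat xs(V, Ci);
  const double* wp = REAL(w);
  arma::mat wt(Ci, Co);
  for (int l = 0; l < k; ++l) for (int j = 0; j < k; ++j)
    for (int i = 0; i < k; ++i) {
      shift_copy(REAL(x), X, Y, Z, Ci, i - p, j - p, l - p, xs.memptr());
      for (int co = 0; co < Co; ++co)
        for (int ci = 0; ci < Ci; ++ci)
          wt(ci, co) = wp[i + k * (j + k * ((size_t)l + k * (ci + (size_t)Ci * co)))];
      ym += xs * wt;
    }
  return res;
}

static List conv3s1_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim");
  const int X = dxd[0], Y = dxd[1], Z = dxd[2], Ci = dxd[3];
  const int k = dwd[0], Co = dwd[4], p = (k - 1) / 2;
  const arma::uword V = (arma::uword)X * Y * Z;
  arma::fmat xf(V, Ci), dyf(V, Co);
  std::copy(REAL(x), REAL(x) + V * Ci, xf.memptr());
  std::copy(REAL(dy), REAL(dy) + V * Co, dyf.memptr());
  NumericVector dxv(V * Ci), dwv((size_t)k * k * k * Ci * Co);
  dxv.attr("dim") = dxd; dwv.attr("dim") = dwd;
  arma::fmat xs(V, Ci), dxs(V, Ci), dxacc(V, Ci, arma::fill::zeros);
  double* dwp = REAL(dwv);
  const double* wp = REAL(w);
  arma::fmat wt(Ci, Co);
  for (int l = 0; l < k; ++l) for (int j = 0; j < k; ++j)
    for (int i = 0; i < k; ++i) {
      shift_copy_f(xf.memptr(), X, Y, Z, Ci, i - p, j - p, l - p,
                   xs.memptr());
      arma::fmat dwt = xs.t() * dyf;           // Ci x Co
      for (int co = 0; co < Co; ++co)
        for (int ci = 0; ci < Ci; ++ci) {
          dwp[i + k * (j + k * ((size_t)l + k * (ci + (size_t)Ci * co)))] =
            dwt(ci, co);
          wt(ci, co) = (float)wp[i + k * (j + k * ((size_t)l + k * (ci + (size_t)Ci * co)))];
        }
      dxs = dyf * wt.t();                      // V x Ci
      shift_add_f(dxs.memptr(), X, Y, Z, Ci, i - p, j - p, l - p,
                  dxacc.memptr());
    }
  std::copy(dxacc.begin(), dxacc.end(), REAL(dxv));
  return List::create(_["dx"] = dxv, _["dw"] = dwv);
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, int stride) {
  if (stride == 1) return conv3s1_fwd(x, w);
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int X = dx[0], Y = dx[1], Z = dx[2], Ci = dx[3];
  const int k = dw[0], Co = dw[4];
  if (dw[3] != Ci) stop("conv3d: input has %d channels, kernel expects %d", Ci, dw[3]);
  const int Xo = outDim(X, k, stride), Yo = outDim(Y, k, stride), Zo = outDim(Z, k, stride);
  arma::mat col;
  im2col3(REAL(x), X, Y, Z, Ci, k, stride, col);
  arma::mat wm(const_cast<double*>(REAL(w)), k * k * k * Ci, Co, false, true);
  arma::mat out = col.t() * wm;      // (V x Co), column-major == (Xo,Yo,Zo,Co)
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return res;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy, int stride) {
  if (stride == 1) return conv3s1_bwd(x, w, dy);
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim"), dyd = dy.attr("dim");
  const int X = dxd[0], Y = dxd[1], Z = dxd[2], Ci = dxd[3];
  const int k = dwd[0], Co = dwd[4];
  const arma::uword V = (arma::uword)dyd[0] * dyd[1] * dyd[2];
  arma::mat col;
  im2col3(REAL(x), X, Y, Z, Ci, k, stride, col);
  arma::mat dym(const_cast<double*>(REAL(dy)), V, Co, false, true);
  arma::mat dwm = col * dym;                       // K x Co
  arma::mat wm(const_cast<double*>(REAL(w)), k * k * k * Ci, Co, false, true);
  arma::mat dcol = wm * dym.t();                   // K x V
  NumericVector dxv((size_t)X * Y * Z * Ci);
  col2im3(dcol, X, Y, Z, Ci, k, stride, REAL(dxv));
  dxv.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  NumericVector dwv(dwm.begin(), dwm.end());
  dwv.attr("dim") = dwd;
  return List::create(_["dx"] = dxv, _["dw"] = dwv);
}

// ---- fused batch-norm and ReLU helpers -------------------------------------

// y = gamma * (x - mean)/sqrt(var + eps) + beta over all voxels per channel
// returns list(y, xhat, mean, istd) in training mode; eval uses given stats
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mean_, NumericVector var_, double eps,
                bool use_batch_stats) {
  IntegerVector d = x.attr("dim");
  const size_t C = d[d.size() - 1];
  const size_t n = x.size() / C;
  NumericVector y(x.size()), xh;
  y.attr("dim") = d;
  NumericVector mu(C), istd(C);
  const double* xp = REAL(x);
  if (use_batch_stats) {
    for (size_t c = 0; c < C; ++c) {
      const double* xc = xp + n * c;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu[c] = s / n;
      istd[c] = 1.0 / std::sqrt(s2 / n - mu[c] * mu[c] + eps);
    }
  } else {
    for (size_t c = 0; c < C; ++c) {
      mu[c] = mean_[c];
      istd[c] = 1.0 / std::sqrt(var_[c] + eps);
    }
  }
  if (use_batch_stats) { xh = NumericVector(x.size()); xh.attr("dim") = d; }
  double* yp = REAL(y);
  for (size_t c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    const double* xc = xp + n * c;
    double* yc = yp + n * c;
    if (use_batch_stats) {
      double* hc = REAL(xh) + n * c;
      for (size_t i = 0; i < n; ++i) {
        hc[i] = (xc[i] - m) * is;
        yc[i] = g * hc[i] + b;
      }
    } else {
      for (size_t i = 0; i < n; ++i) yc[i] = g * (xc[i] - m) * is + b;
    }
  }
  return List::create(_["y"] = y, _["xh"] = xh, _["mean"] = mu,
                      _["istd"] = istd);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector dy, NumericVector xh, NumericVector gamma,
                NumericVector istd) {
  IntegerVector d = dy.attr("dim");
  const size_t C = d[d.size() - 1];
  const size_t n = dy.size() / C;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = d;
  const double* dyp = REAL(dy); const double* hp = REAL(xh);
  double* dxp = REAL(dx);
  for (size_t c = 0; c < C; ++c) {
    const double* dc = dyp + n * c; const double* hc = hp + n * c;
    double sg = 0, sb = 0;
    for (size_t i = 0; i < n; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double mg = sg / n, mb = sb / n, f = gamma[c] * istd[c];
    double* xc = dxp + n * c;
    for (size_t i = 0; i < n; ++i)
      xc[i] = f * (dc[i] - mb - hc[i] * mg);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); double* yp = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* dp = REAL(dy); const double* yp = REAL(y);
  double* xp = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) xp[i] = yp[i] > 0 ? dp[i] : 0;
  return dx;
}

// ---- depthwise 2D convolution on slice-folded maps -------------------------

// [[Rcpp::export(name = ".cpp_dwconv2d_fwd")]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int X = dx[0], Y = dx[1], C = dx[2], M = dx[3];
  const int kx = dw[0], ky = dw[1];
  const int px = (kx - 1) / 2, py = (ky - 1) / 2;
  NumericVector out((size_t)X * Y * C * M);
  out.attr("dim") = dx;
  const double* xp = REAL(x); const double* wp = REAL(w);
  const double* bp = REAL(b); double* op = REAL(out);
  for (int m = 0; m < M; ++m)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)X * Y * (c + (size_t)C * m);
      double* oc = op + (size_t)X * Y * (c + (size_t)C * m);
      const double* wc = wp + (size_t)kx * ky * c;
      for (int y = 0; y < Y; ++y)
        for (int x0 = 0; x0 < X; ++x0) {
          double acc = bp[c];
          for (int j = 0; j < ky; ++j) {
            const int yy = y + j - py;
            if (yy < 0 || yy >= Y) continue;
            for (int i = 0; i < kx; ++i) {
              const int xx = x0 + i - px;
              if (xx >= 0 && xx < X) acc += wc[i + kx * j] * xc[xx + (size_t)X * yy];
            }
          }
          oc[x0 + (size_t)X * y] = acc;
        }
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_dwconv2d_bwd")]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim");
  const int X = dxd[0], Y = dxd[1], C = dxd[2], M = dxd[3];
  const int kx = dwd[0], ky = dwd[1];
  const int px = (kx - 1) / 2, py = (ky - 1) / 2;
  NumericVector dxv((size_t)X * Y * C * M), dwv((size_t)kx * ky * C), dbv(C);
  dxv.attr("dim") = dxd; dwv.attr("dim") = dwd;
  const double* xp = REAL(x); const double* wp = REAL(w); const double* dyp = REAL(dy);
  double* dxp = REAL(dxv); double* dwp = REAL(dwv); double* dbp = REAL(dbv);
  for (int m = 0; m < M; ++m)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)X * Y * (c + (size_t)C * m);
      const double* gc = dyp + (size_t)X * Y * (c + (size_t)C * m);
      double* dxc = dxp + (size_t)X * Y * (c + (size_t)C * m);
      const double* wc = wp + (size_t)kx * ky * c;
      double* dwc = dwp + (size_t)kx * ky * c;
      for (int y = 0; y < Y; ++y)
        for (int x0 = 0; x0 < X; ++x0) {
          const double g = gc[x0 + (size_t)X * y];
          dbp[c] += g;
          for (int j = 0; j < ky; ++j) {
            const int yy = y + j - py;
            if (yy < 0 || yy >= Y) continue;
            for (int i = 0; i < kx; ++i) {
              const int xx = x0 + i - px;
              if (xx >= 0 && xx < X) {
                dwc[i + kx * j] += g * xc[xx + (size_t)X * yy];
                dxc[xx + (size_t)X * yy] += g * wc[i + kx * j];
              }
            }
          }
        }
    }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// ---- trilinear / nearest resizing ------------------------------------------

static void lin_coef(int n_in, int n_out, std::vector<int>& i0,
                     std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  const double s = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) * s - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    i0[o] = (int)std::floor(src);
    i1[o] = std::min(i0[o] + 1, n_in - 1);
    w1[o] = src - i0[o];
  }
}

// separable trilinear resize: one linear-interpolation pass per axis
// (exactly equivalent to 8-point trilinear since the weights factorize)

static std::vector<double> resize_axis(const std::vector<double>& src,
                                       const int dims[4], int axis, int n_out,
                                       bool forward) {
  const int n_in = dims[axis];
  size_t pre = 1, post = 1;
  for (int a = 0; a < axis; ++a) pre *= dims[a];
  for (int a = axis + 1; a < 4; ++a) post *= dims[a];
  std::vector<int> i0, i1;
  std::vector<double> w1;
  lin_coef(n_in, n_out, i0, i1, w1);
  const int n_from = forward ? n_in : n_out;
  const int n_to = forward ? n_out : n_in;
  std::vector<double> dst(pre * n_to * post, 0.0);
  for (size_t p = 0; p < post; ++p) {
    const double* sp = src.data() + p * pre * n_from;
    double* dp = dst.data() + p * pre * n_to;
    if (forward) {
      for (int o = 0; o < n_out; ++o) {
        const double w = w1[o];
        const double* a0 = sp + (size_t)i0[o] * pre;
        const double* a1 = sp + (size_t)i1[o] * pre;
        double* dd = dp + (size_t)o * pre;
        for (size_t q = 0; q < pre; ++q)
          dd[q] = (1.0 - w) * a0[q] + w * a1[q];
      }
    } else {
      for (int o = 0; o < n_out; ++o) {
        const double w = w1[o];
        const double* gg = sp + (size_t)o * pre;
        double* a0 = dp + (size_t)i0[o] * pre;
        double* a1 = dp + (size_t)i1[o] * pre;
        for (size_t q = 0; q < pre; ++q) {
          a0[q] += (1.0 - w) * gg[q];
          a1[q] += w * gg[q];
        }
      }
    }
  }
  return dst;
}

// [[Rcpp::export(name = ".cpp_trilinear_resize")]]
NumericVector cpp_trilinear_resize(NumericVector x, IntegerVector newdim) {
  IntegerVector d = x.attr("dim");
  int dims[4] = {d[0], d[1], d[2], d[3]};
  std::vector<double> buf(REAL(x), REAL(x) + x.size());
  for (int axis = 0; axis < 3; ++axis) {
    if (dims[axis] == newdim[axis]) continue;
    buf = resize_axis(buf, dims, axis, newdim[axis], true);
    dims[axis] = newdim[axis];
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], dims[3]);
  return out;
}

// [[Rcpp::export(name = ".cpp_trilinear_resize_bwd")]]
NumericVector cpp_trilinear_resize_bwd(NumericVector dy, IntegerVector indim) {
  IntegerVector d = dy.attr("dim");
  int dims[4] = {d[0], d[1], d[2], d[3]};
  std::vector<double> buf(REAL(dy), REAL(dy) + dy.size());
  // transpose of the forward passes, applied in reverse axis order; the
  // lin_coef map must be the forward one (in -> out) for each axis
  for (int axis = 2; axis >= 0; --axis) {
    if (dims[axis] == indim[axis]) continue;
    int fdims[4] = {dims[0], dims[1], dims[2], dims[3]};
    fdims[axis] = indim[axis];         // pretend input dims for coef mapping
    buf = resize_axis(buf, fdims, axis, dims[axis], false);
    dims[axis] = indim[axis];
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], dims[3]);
  return out;
}

// [[Rcpp::export(name = ".cpp_nearest_resize")]]
NumericVector cpp_nearest_resize(NumericVector x, IntegerVector newdim) {
  IntegerVector d = x.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  const int C = d.size() == 4 ? (int)d[3] : 1;
  const int Xo = newdim[0], Yo = newdim[1], Zo = newdim[2];
  std::vector<int> xi(Xo), yi(Yo), zi(Zo);
  for (int o = 0; o < Xo; ++o) xi[o] = std::min(X - 1, (int)std::floor((o + 0.5) * X / Xo));
  for (int o = 0; o < Yo; ++o) yi[o] = std::min(Y - 1, (int)std::floor((o + 0.5) * Y / Yo));
  for (int o = 0; o < Zo; ++o) zi[o] = std::min(Z - 1, (int)std::floor((o + 0.5) * Z / Zo));
  NumericVector out((size_t)Xo * Yo * Zo * C);
  if (d.size() == 4)
    out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  else
    out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  const double* xp = REAL(x); double* op = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo)
          op[xo + (size_t)Xo * (yo + (size_t)Yo * (zo + (size_t)Zo * c))] =
            xp[xi[xo] + (size_t)X * (yi[yo] + (size_t)Y * (zi[zo] + (size_t)Z * c))];
  return out;
}

// ---- 3D connected components (6 or 26 connectivity) ------------------------

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  IntegerVector lab((size_t)X * Y * Z);
  lab.attr("dim") = d;
  const int* mp = LOGICAL(mask);
  int* lp = INTEGER(lab);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dyy = -1; dyy <= 1; ++dyy)
      for (int dxx = -1; dxx <= 1; ++dxx) {
        if (!dxx && !dyy && !dz) continue;
        if (connectivity == 6 && std::abs(dxx) + std::abs(dyy) + std::abs(dz) != 1) continue;
        nb.push_back({dxx, dyy, dz});
      }
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t v = 0; v < (size_t)X * Y * Z; ++v) {
    if (!mp[v] || lp[v]) continue;
    ++cur;
    stack.clear(); stack.push_back(v); lp[v] = cur;
    while (!stack.empty()) {
      const size_t u = stack.back(); stack.pop_back();
      const int ux = u % X, uy = (u / X) % Y, uz = u / ((size_t)X * Y);
      for (auto& o : nb) {
        const int nx = ux + o[0], ny = uy + o[1], nz = uz + o[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const size_t w = nx + (size_t)X * (ny + (size_t)Y * nz);
        if (mp[w] && !lp[w]) { lp[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// ---- binary ball morphology -------------------------------------------------

static std::vector<std::array<int, 3>> ball_offsets(int r) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r) off.push_back({dx, dy, dz});
  return off;
}

// `outside` is the value assumed beyond the grid border: background for
// dilation, but foreground for the erosion half of a closing so that
// regions touching the border are not shaved inward
// [[Rcpp::export(name = ".cpp_binary_morph")]]
LogicalVector cpp_binary_morph(LogicalVector mask, int radius, bool dilate,
                               bool outside = false) {
  IntegerVector d = mask.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  LogicalVector out((size_t)X * Y * Z);
  out.attr("dim") = d;
  const int* mp = LOGICAL(mask);
  int* op = LOGICAL(out);
  auto off = ball_offsets(radius);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        bool hit = dilate ? false : true;
        for (auto& o : off) {
          const int nx = x + o[0], ny = y + o[1], nz = z + o[2];
          bool v;
          if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
            v = outside;
          else
            v = mp[nx + (size_t)X * (ny + (size_t)Y * nz)];
          if (dilate && v) { hit = true; break; }
          if (!dilate && !v) { hit = false; break; }
        }
        op[x + (size_t)X * (y + (size_t)Y * z)] = hit;
      }
  return out;
}

// ---- slice-wise hole filling (xy planes) ------------------------------------

// [[Rcpp::export(name = ".cpp_fill_holes_slicewise")]]
LogicalVector cpp_fill_holes_slicewise(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  LogicalVector out(clone(mask));
  int* op = LOGICAL(out);
  std::vector<char> reach((size_t)X * Y);
  std::vector<int> stack;
  for (int z = 0; z < Z; ++z) {
    int* sl = op + (size_t)X * Y * z;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int x = 0; x < X; ++x) {
      if (!sl[x]) { reach[x] = 1; stack.push_back(x); }
      const int top = x + X * (Y - 1);
      if (!sl[top] && !reach[top]) { reach[top] = 1; stack.push_back(top); }
    }
    for (int y = 0; y < Y; ++y) {
      const int l = X * y, r = (X - 1) + X * y;
      if (!sl[l] && !reach[l]) { reach[l] = 1; stack.push_back(l); }
      if (!sl[r] && !reach[r]) { reach[r] = 1; stack.push_back(r); }
    }
    while (!stack.empty()) {
      const int u = stack.back(); stack.pop_back();
      const int ux = u % X, uy = u / X;
      const int nbs[4][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1}};
      for (auto& nb2 : nbs) {
        const int nx = ux + nb2[0], ny = uy + nb2[1];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y) continue;
        const int w = nx + X * ny;
        if (!sl[w] && !reach[w]) { reach[w] = 1; stack.push_back(w); }
      }
    }
    for (int i = 0; i < X * Y; ++i)
      if (!sl[i] && !reach[i]) sl[i] = 1;  // enclosed background -> foreground
  }
  return out;
}

// ---- exact anisotropic squared Euclidean distance transform -----------------
// Felzenszwalb & Huttenlocher lower-envelope scan, one pass per axis.

static void edt1d(std::vector<double>& f, double sp, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& zb) {
  const int n = f.size();
  d.assign(n, 0.0);
  v.assign(n, 0); zb.assign(n + 1, 0.0);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  const double s2 = sp * sp;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
  f = d;
}

// sites: logical array of "zero-distance" voxels; returns distances in mm
// [[Rcpp::export(name = ".cpp_distance_to_sites")]]
NumericVector cpp_distance_to_sites(LogicalVector sites, NumericVector spacing) {
  IntegerVector d = sites.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  NumericVector out((size_t)X * Y * Z);
  out.attr("dim") = d;
  double* op = REAL(out);
  const int* sp = LOGICAL(sites);
  // large finite sentinel: true infinity breaks the lower-envelope
  // intersection arithmetic (INF - INF) on site-free rows
  const double BIG = 1e30;
  for (size_t v = 0; v < (size_t)X * Y * Z; ++v) op[v] = sp[v] ? 0.0 : BIG;
  std::vector<double> f, dd, zb; std::vector<int> vv;
  // x axis
  f.resize(X);
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) {
    double* row = op + (size_t)X * (y + (size_t)Y * z);
    f.assign(row, row + X);
    edt1d(f, spacing[0], dd, vv, zb);
    std::copy(f.begin(), f.end(), row);
  }
  // y axis
  f.resize(Y);
  for (int z = 0; z < Z; ++z) for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) f[y] = op[x + (size_t)X * (y + (size_t)Y * z)];
    edt1d(f, spacing[1], dd, vv, zb);
    for (int y = 0; y < Y; ++y) op[x + (size_t)X * (y + (size_t)Y * z)] = f[y];
  }
  // z axis
  f.resize(Z);
  for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    for (int z = 0; z < Z; ++z) f[z] = op[x + (size_t)X * (y + (size_t)Y * z)];
    edt1d(f, spacing[2], dd, vv, zb);
    for (int z = 0; z < Z; ++z) op[x + (size_t)X * (y + (size_t)Y * z)] = f[z];
  }
  for (size_t v = 0; v < (size_t)X * Y * Z; ++v) op[v] = std::sqrt(op[v]);
  return out;
}

// ---- maximum pairwise distance (Feret diameter) -----------------------------

// pts: n x 3 matrix of coordinates in mm
// [[Rcpp::export(name = ".cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(i, 0) - pts(j, 0);
      const double dy = pts(i, 1) - pts(j, 1);
      const double dz = pts(i, 2) - pts(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
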