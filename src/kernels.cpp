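// Low-level numerical kernels: 3D convolution (im2col + GEMM), stride-2
// transposed convolution, 2x average pooling, anisotropic squared Euclidean
// distance transform, and 26-connected component labelling.
//
// Array convention throughout: R arrays in column-major order with
// dim = (X, Y, Z, C); flat index = x + X*(y + Y*(z + Z*c)), 0-based here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int pad, int stride, int dil) {
  return (n + 2 * pad - (dil * (k - 1) + 1)) / stride + 1;
}

// ceil(a / b) for b > 0 and any sign of a
static inline int ceil_div(int a, int b) {
  return a >= 0 ? (a + b - 1) / b : -((-a) / b);
}

// Build the patch matrix with columns = kernel taps (k^3 * Ci) and rows =
// output voxels, so writes are contiguous down each column. Column index
// = kx + k*(ky + k*(kz + k*ci)), matching the column-major flatten of an R
// weight array with dim (k, k, k, Ci, Co).
// single precision internally: convolution arithmetic does not need the
// last 8 digits and fp32 halves the memory traffic of the patch matrices
static arma::fmat im2colT(const double* x, int X, int Y, int Z, int Ci,
                          int k, int stride, int dil, int pad,
                          int Xo, int Yo, int Zo) {
  const long N = (long)Xo * Yo * Zo;
  arma::fmat colT(N, (long)k * k * k * Ci, arma::fill::zeros);
  const long XY = (long)X * Y;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (long)ci * XY * Z;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          float* cp = colT.colptr(kx + k * (ky + k * (kz + (long)k * ci)));
          const int offx = kx * dil - pad;
          const int offy = ky * dil - pad;
          const int offz = kz * dil - pad;
          const int xo_lo = std::max(0, ceil_div(-offx, stride));
          const int xo_hi = std::min(Xo - 1, (X - 1 - offx) / stride);
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride + offz;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride + offy;
              if (yi < 0 || yi >= Y) continue;
              float* dst = cp + (long)Xo * (yo + (long)Yo * zo);
              const double* srcbase = xc + X * ((long)yi + (long)Y * zi);
              for (int xo = xo_lo; xo <= xo_hi; ++xo)
                dst[xo] = (float)srcbase[xo * stride + offx];
            }
          }
        }
  }
  return colT;
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector dims,
                         const arma::mat& Wmat, NumericVector b,
                         int k, int stride, int dil) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Ci = dims[3];
  const int pad = dil * (k - 1) / 2;
  const int Xo = out_extent(X, k, pad, stride, dil);
  const int Yo = out_extent(Y, k, pad, stride, dil);
  const int Zo = out_extent(Z, k, pad, stride, dil);
  const int N = Xo * Yo * Zo;
  const int Co = Wmat.n_cols;
  arma::fmat colT = im2colT(REAL(x), X, Y, Z, Ci, k, stride, dil, pad,
                            Xo, Yo, Zo);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wmat);
  arma::fmat out = colT * Wf;                  // N x Co
  NumericVector y((long)N * Co);
  double* yp = REAL(y);
  for (int co = 0; co < Co; ++co) {
    const float* oc = out.colptr(co);
    const double bc = b[co];
    double* yc = yp + (long)co * N;
    for (long n = 0; n < N; ++n) yc[n] = (double)oc[n] + bc;
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector dims, const arma::mat& Wmat,
                NumericVector dy, int k, int stride, int dil,
                bool need_dx) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Ci = dims[3];
  const int pad = dil * (k - 1) / 2;
  const int Xo = out_extent(X, k, pad, stride, dil);
  const int Yo = out_extent(Y, k, pad, stride, dil);
  const int Zo = out_extent(Z, k, pad, stride, dil);
  const int N = Xo * Yo * Zo;
  const int Co = Wmat.n_cols;
  arma::fmat colT = im2colT(REAL(x), X, Y, Z, Ci, k, stride, dil, pad,
                            Xo, Yo, Zo);
  arma::mat dymd(REAL(dy), N, Co, false, true);  // reuse memory
  arma::fmat dym = arma::conv_to<arma::fmat>::from(dymd);
  arma::fmat dWf = colT.t() * dym;               // (k^3*Ci) x Co
  arma::mat dW = arma::conv_to<arma::mat>::from(dWf);
  arma::rowvec db = arma::sum(dymd, 0);
  if (!need_dx) {
    return List::create(_["dx"] = R_NilValue, _["dW"] = dW,
                        _["db"] = NumericVector(db.begin(), db.end()));
  }
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wmat);
  arma::fmat dcolT = dym * Wf.t();               // N x (k^3*Ci)

  NumericVector dx(x.size());
  double* dxp = REAL(dx);
  const long XY = (long)X * Y;
  for (int ci = 0; ci < Ci; ++ci) {
    double* dxc = dxp + (long)ci * XY * Z;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const float* cp =
              dcolT.colptr(kx + k * (ky + k * (kz + (long)k * ci)));
          const int offx = kx * dil - pad;
          const int offy = ky * dil - pad;
          const int offz = kz * dil - pad;
          const int xo_lo = std::max(0, ceil_div(-offx, stride));
          const int xo_hi = std::min(Xo - 1, (X - 1 - offx) / stride);
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride + offz;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride + offy;
              if (yi < 0 || yi >= Y) continue;
              const float* src = cp + (long)Xo * (yo + (long)Yo * zo);
              double* dstbase = dxc + X * ((long)yi + (long)Y * zi);
              for (int xo = xo_lo; xo <= xo_hi; ++xo)
                dstbase[xo * stride + offx] += (double)src[xo];
            }
          }
        }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution, kernel 2, stride 2 (exact 2x upsampling).
// W has dim (2, 2, 2, Ci, Co) flattened column-major. Implemented as a
// GEMM over input voxels: patches(N, tap + 8*co) = x(N, ci) * Wr, then
// each tap column scatters to one of the 8 output sub-lattices.

// reorder W (8, Ci, Co) -> (Ci, 8*Co)
static arma::fmat upconv_wmat(const double* wp, int Ci, int Co) {
  arma::fmat Wr(Ci, 8 * Co);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int t = 0; t < 8; ++t)
        Wr(ci, t + 8 * co) = (float)wp[t + 8L * (ci + (long)Ci * co)];
  return Wr;
}

// [[Rcpp::export(name = ".upconv_fwd")]]
NumericVector upconv_fwd(NumericVector x, IntegerVector dims,
                         NumericVector W, NumericVector b) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Ci = dims[3];
  const int Co = b.size();
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const long N = (long)X * Y * Z;
  arma::mat xmd(REAL(x), N, Ci, false, true);
  arma::fmat xm = arma::conv_to<arma::fmat>::from(xmd);
  arma::fmat patches = xm * upconv_wmat(REAL(W), Ci, Co);  // N x 8Co
  NumericVector y((long)Xo * Yo * Zo * Co);
  double* yp = REAL(y);
  for (int co = 0; co < Co; ++co) {
    double* yc = yp + (long)co * Xo * Yo * Zo;
    const long nvo = (long)Xo * Yo * Zo;
    for (long v = 0; v < nvo; ++v) yc[v] = b[co];
    for (int t = 0; t < 8; ++t) {
      const int kx = t & 1, ky = (t >> 1) & 1, kz = (t >> 2) & 1;
      const float* pc = patches.colptr(t + 8 * co);
      for (int z = 0; z < Z; ++z)
        for (int y_ = 0; y_ < Y; ++y_) {
          const float* src = pc + X * ((long)y_ + (long)Y * z);
          double* dst = yc + kx +
              (long)Xo * ((2 * y_ + ky) + (long)Yo * (2 * z + kz));
          for (int x_ = 0; x_ < X; ++x_) dst[2 * x_] += (double)src[x_];
        }
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return y;
}

// [[Rcpp::export(name = ".upconv_bwd")]]
List upconv_bwd(NumericVector x, IntegerVector dims, NumericVector W,
                NumericVector dy, int Co) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Ci = dims[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const long N = (long)X * Y * Z;
  const double* dyp = REAL(dy);
  // gather output gradient into patch form (N x 8Co)
  arma::fmat dpat(N, 8 * Co);
  NumericVector db(Co);
  for (int co = 0; co < Co; ++co) {
    const double* dyc = dyp + (long)co * Xo * Yo * Zo;
    double s = 0.0;
    const long nvo = (long)Xo * Yo * Zo;
    for (long v = 0; v < nvo; ++v) s += dyc[v];
    db[co] = s;
    for (int t = 0; t < 8; ++t) {
      const int kx = t & 1, ky = (t >> 1) & 1, kz = (t >> 2) & 1;
      float* pc = dpat.colptr(t + 8 * co);
      for (int z = 0; z < Z; ++z)
        for (int y_ = 0; y_ < Y; ++y_) {
          float* dst = pc + X * ((long)y_ + (long)Y * z);
          const double* src = dyc + kx +
              (long)Xo * ((2 * y_ + ky) + (long)Yo * (2 * z + kz));
          for (int x_ = 0; x_ < X; ++x_) dst[x_] = (float)src[2 * x_];
        }
    }
  }
  arma::mat xmd(REAL(x), N, Ci, false, true);
  arma::fmat xm = arma::conv_to<arma::fmat>::from(xmd);
  arma::fmat Wr = upconv_wmat(REAL(W), Ci, Co);
  arma::fmat dWr = xm.t() * dpat;              // Ci x 8Co
  arma::fmat dxm = dpat * Wr.t();              // N x Ci
  NumericVector dW(W.size());
  double* dWp = REAL(dW);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int t = 0; t < 8; ++t)
        dWp[t + 8L * (ci + (long)Ci * co)] = (double)dWr(ci, t + 8 * co);
  NumericVector dx(x.size());
  double* dxp = REAL(dx);
  for (int ci = 0; ci < Ci; ++ci) {
    const float* sc = dxm.colptr(ci);
    double* dc = dxp + (long)ci * N;
    for (long v = 0; v < N; ++v) dc[v] = (double)sc[v];
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Instance normalisation: per-channel normalisation over all voxels of
// one sample, with affine terms.
// [[Rcpp::export(name = ".inorm_fwd_c")]]
List inorm_fwd_c(NumericVector x, IntegerVector dims, NumericVector gamma,
                 NumericVector beta) {
  const long n = (long)dims[0] * dims[1] * dims[2];
  const int C = dims[3];
  NumericVector y(x.size()), xhat(x.size());
  NumericVector istd(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* hp = REAL(xhat);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)c * n;
    double* yc = yp + (long)c * n;
    double* hc = hp + (long)c * n;
    double s = 0, s2 = 0;
    for (long v = 0; v < n; ++v) { s += xc[v]; s2 += xc[v] * xc[v]; }
    const double mu = s / n;
    const double var = s2 / n - mu * mu;
    const double is = 1.0 / std::sqrt(var + 1e-5);
    istd[c] = is;
    const double g = gamma[c], be = beta[c];
    for (long v = 0; v < n; ++v) {
      hc[v] = (xc[v] - mu) * is;
      yc[v] = g * hc[v] + be;
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export(name = ".inorm_bwd_c")]]
List inorm_bwd_c(NumericVector dy, IntegerVector dims, NumericVector xhat,
                 NumericVector istd, NumericVector gamma) {
  const long n = (long)dims[0] * dims[1] * dims[2];
  const int C = dims[3];
  NumericVector dx(dy.size());
  NumericVector dgamma(C), dbeta(C);
  const double* dyp = REAL(dy);
  const double* hp = REAL(xhat);
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dyp + (long)c * n;
    const double* hc = hp + (long)c * n;
    double* dxc = dxp + (long)c * n;
    double sdy = 0, sdyh = 0;
    for (long v = 0; v < n; ++v) {
      sdy += dyc[v];
      sdyh += dyc[v] * hc[v];
    }
    dgamma[c] = sdyh;
    dbeta[c] = sdy;
    const double g = gamma[c], is = istd[c];
    const double mdy = sdy / n, mdyh = sdyh / n;
    for (long v = 0; v < n; ++v)
      dxc[v] = g * is * (dyc[v] - mdy - hc[v] * mdyh);
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2x2 average pooling, stride 2.
// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y((long)Xo * Yo * Zo * C);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)c * X * Y * Z;
    double* yc = yp + (long)c * Xo * Yo * Zo;
    for (int z = 0; z < Zo; ++z)
      for (int y_ = 0; y_ < Yo; ++y_)
        for (int x_ = 0; x_ < Xo; ++x_) {
          double s = 0.0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx)
                s += xc[(2 * x_ + kx) +
                        X * ((long)(2 * y_ + ky) + (long)Y * (2 * z + kz))];
          yc[x_ + Xo * ((long)y_ + (long)Yo * z)] = s / 8.0;
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
NumericVector avgpool_bwd(NumericVector dy, IntegerVector outdims) {
  const int X = outdims[0], Y = outdims[1], Z = outdims[2], C = outdims[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector dx((long)X * Y * Z * C);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  for (int c = 0; c < C; ++c) {
    double* dxc = dxp + (long)c * X * Y * Z;
    const double* dyc = dyp + (long)c * Xo * Yo * Zo;
    for (int z = 0; z < Zo; ++z)
      for (int y_ = 0; y_ < Yo; ++y_)
        for (int x_ = 0; x_ < Xo; ++x_) {
          const double g = dyc[x_ + Xo * ((long)y_ + (long)Yo * z)] / 8.0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx)
                dxc[(2 * x_ + kx) +
                    X * ((long)(2 * y_ + ky) + (long)Y * (2 * z + kz))] = g;
        }
  }
  dx.attr("dim") = outdims;
  return dx;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (Felzenszwalb-Huttenlocher
// lower-envelope of parabolas, run separably along each axis with the axis'
// physical spacing). feature == 1 marks the zero-distance set.

static void dt1d(std::vector<double>& f, std::vector<double>& d, double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const double pq = q * h, pv = v[k] * h;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2 * pq - 2 * pv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double pq = q * h;
    while (z[k + 1] < pq) ++k;
    const double diff = pq - v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector feature, IntegerVector dims,
                       NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long n = (long)X * Y * Z;
  NumericVector D(n);
  double* d = REAL(D);
  // large finite sentinel (keeps the parabola intersections finite on
  // scan lines without any feature voxel)
  const double BIG = 1e30;
  for (long i = 0; i < n; ++i) d[i] = feature[i] ? 0.0 : BIG;

  std::vector<double> f, g;
  // along x
  f.resize(X); g.resize(X);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      const long off = X * ((long)y + (long)Y * z);
      for (int x = 0; x < X; ++x) f[x] = d[off + x];
      dt1d(f, g, spacing[0]);
      for (int x = 0; x < X; ++x) d[off + x] = g[x];
    }
  // along y
  f.resize(Y); g.resize(Y);
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = d[x + X * ((long)y + (long)Y * z)];
      dt1d(f, g, spacing[1]);
      for (int y = 0; y < Y; ++y) d[x + X * ((long)y + (long)Y * z)] = g[y];
    }
  // along z
  f.resize(Z); g.resize(Z);
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = d[x + X * ((long)y + (long)Y * z)];
      dt1d(f, g, spacing[2]);
      for (int z = 0; z < Z; ++z) d[x + X * ((long)y + (long)Y * z)] = g[z];
    }
  D.attr("dim") = dims;
  return D;
}

// 26-connected component labelling; labels assigned in order of first
// encounter in a column-major scan (x fastest). 0 = background.
// [[Rcpp::export(name = ".label_cc26")]]
IntegerVector label_cc26(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long n = (long)X * Y * Z;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long> stack;
  for (long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const long cur = stack.back();
      stack.pop_back();
      const int x = cur % X, y = (cur / X) % Y, z = cur / ((long)X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
              continue;
            const long ni = nx + X * ((long)ny + (long)Y * nz);
            if (mask[ni] && lab[ni] == 0) {
              lab[ni] = next;
              stack.push_back(ni);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
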