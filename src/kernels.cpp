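// Low-level 3D kernels: im2col convolution (3x3x3, stride 1, zero pad 1),
// 2x2x2 max pooling, nearest-neighbour x2 upsampling, affine resampling and
// seeded 26-connectivity flood fill. Feature maps are (Nvox x C) matrices
// with voxel linear index i = x + nx*(y + ny*z), 0-based, x fastest
// (native R array order). Single precision internally; R sees doubles.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void check_dims(const IntegerVector& dims) {
  if (dims.size() != 3 || dims[0] < 1 || dims[1] < 1 || dims[2] < 1)
    stop("dims must be three positive integers");
}

// Build the (N x 27*Cin) patch matrix; column (c*27 + k) holds neighbour
// offset k of channel c, zero outside the grid.
static arma::fmat im2col3(const arma::fmat& X, int nx, int ny, int nz) {
  const int N = nx * ny * nz;
  const int Cin = X.n_cols;
  arma::fmat col(N, 27 * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const float* xc = X.colptr(c);
    for (int oz = -1; oz <= 1; ++oz) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          const int k = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
          float* dst = col.colptr(c * 27 + k);
          const int z0 = std::max(0, -oz), z1 = nz - 1 - std::max(0, oz);
          const int y0 = std::max(0, -oy), y1 = ny - 1 - std::max(0, oy);
          const int x0 = std::max(0, -ox), x1 = nx - 1 - std::max(0, ox);
          const int off = ox + nx * (oy + ny * oz);
          for (int z = z0; z <= z1; ++z) {
            for (int y = y0; y <= y1; ++y) {
              const int base = nx * (y + ny * z);
              const float* src = xc + base + off + x0;
              float* d = dst + base + x0;
              const int len = x1 - x0 + 1;
              for (int x = 0; x < len; ++x) d[x] = src[x];
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add transpose of im2col3.
static void col2im3(const arma::fmat& colm, int nx, int ny, int nz,
                    arma::fmat& dX) {
  const int Cin = dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    float* xc = dX.colptr(c);
    for (int oz = -1; oz <= 1; ++oz) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          const int k = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
          const float* src0 = colm.colptr(c * 27 + k);
          const int z0 = std::max(0, -oz), z1 = nz - 1 - std::max(0, oz);
          const int y0 = std::max(0, -oy), y1 = ny - 1 - std::max(0, oy);
          const int x0 = std::max(0, -ox), x1 = nx - 1 - std::max(0, ox);
          const int off = ox + nx * (oy + ny * oz);
          for (int z = z0; z <= z1; ++z) {
            for (int y = y0; y <= y1; ++y) {
              const int base = nx * (y + ny * z);
              float* d = xc + base + off + x0;
              const float* src = src0 + base + x0;
              const int len = x1 - x0 + 1;
              for (int x = 0; x < len; ++x) d[x] += src[x];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fw(const NumericMatrix& X, const IntegerVector& dims,
                            const NumericMatrix& W, const NumericVector& b) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  if (X.nrow() != N) stop("X rows do not match dims");
  const int Cin = X.ncol(), Cout = W.ncol();
  if (W.nrow() != 27 * Cin) stop("W must have 27*Cin rows");
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(X.begin()), N, Cin, false));
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(W.begin()), W.nrow(), Cout, false));
  arma::fmat colm = im2col3(Xf, nx, ny, nz);
  arma::fmat Y = colm * Wf;
  for (int c = 0; c < Cout; ++c) Y.col(c) += (float)b[c];
  NumericMatrix out(N, Cout);
  std::copy(Y.begin(), Y.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(const NumericMatrix& X, const IntegerVector& dims,
                   const NumericMatrix& W, const NumericMatrix& dY) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  const int Cin = X.ncol(), Cout = W.ncol();
  if (dY.nrow() != N || dY.ncol() != Cout) stop("dY shape mismatch");
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(X.begin()), N, Cin, false));
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(W.begin()), W.nrow(), Cout, false));
  arma::fmat dYf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(dY.begin()), N, Cout, false));
  arma::fmat colm = im2col3(Xf, nx, ny, nz);
  arma::fmat dW = colm.t() * dYf;            // (27*Cin x Cout)
  arma::frowvec db = arma::sum(dYf, 0);
  arma::fmat dCol = dYf * Wf.t();            // (N x 27*Cin)
  arma::fmat dX(N, Cin, arma::fill::zeros);
  col2im3(dCol, nx, ny, nz, dX);
  NumericMatrix dXo(N, Cin), dWo(27 * Cin, Cout);
  NumericVector dbo(Cout);
  std::copy(dX.begin(), dX.end(), dXo.begin());
  std::copy(dW.begin(), dW.end(), dWo.begin());
  for (int c = 0; c < Cout; ++c) dbo[c] = db[c];
  return List::create(_["dX"] = dXo, _["dW"] = dWo, _["db"] = dbo);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericMatrix& X, const IntegerVector& dims) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx % 2 || ny % 2 || nz % 2) stop("grid not divisible by 2 for pooling");
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int M = mx * my * mz, C = X.ncol();
  if (X.nrow() != nx * ny * nz) stop("X rows do not match dims");
  NumericMatrix Y(M, C);
  IntegerMatrix idx(M, C);  // 1-based input linear index of the max
  for (int c = 0; c < C; ++c) {
    for (int z = 0; z < mz; ++z) {
      for (int y = 0; y < my; ++y) {
        for (int x = 0; x < mx; ++x) {
          const int o = x + mx * (y + my * z);
          double best = -1e300; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int i = (2 * x + dx) + nx * ((2 * y + dy) + ny * (2 * z + dz));
                const double v = X(i, c);
                if (v > best) { best = v; bi = i; }
              }
          Y(o, c) = best;
          idx(o, c) = bi + 1;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(const IntegerMatrix& idx, const NumericMatrix& dY,
                             int n_in) {
  const int M = dY.nrow(), C = dY.ncol();
  if (idx.nrow() != M || idx.ncol() != C) stop("idx/dY mismatch");
  NumericMatrix dX(n_in, C);
  for (int c = 0; c < C; ++c)
    for (int o = 0; o < M; ++o)
      dX(idx(o, c) - 1, c) += dY(o, c);
  return dX;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample_fw(const NumericMatrix& X, const IntegerVector& dims) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int C = X.ncol();
  if (X.nrow() != nx * ny * nz) stop("X rows do not match dims");
  NumericMatrix Y(ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    for (int z = 0; z < oz; ++z) {
      for (int y = 0; y < oy; ++y) {
        const int ib = nx * ((y / 2) + ny * (z / 2));
        const int ob = ox * (y + oy * z);
        for (int x = 0; x < ox; ++x)
          Y(ob + x, c) = X(ib + x / 2, c);
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample_bw(const NumericMatrix& dY, const IntegerVector& dims) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int C = dY.ncol();
  if (dY.nrow() != ox * oy * oz) stop("dY rows do not match upsampled dims");
  NumericMatrix dX(nx * ny * nz, C);
  for (int c = 0; c < C; ++c) {
    for (int z = 0; z < oz; ++z) {
      for (int y = 0; y < oy; ++y) {
        const int ib = nx * ((y / 2) + ny * (z / 2));
        const int ob = ox * (y + oy * z);
        for (int x = 0; x < ox; ++x)
          dX(ib + x / 2, c) += dY(ob + x, c);
      }
    }
  }
  return dX;
}

// Resample a volume through an affine voxel map: output voxel (0-based
// index triplet v) samples the input at continuous 0-based index
// M[,1:3] %*% v + M[,4]. Trilinear or nearest; outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(const NumericVector& vol,
                                  const IntegerVector& dims,
                                  const NumericMatrix& M,
                                  const IntegerVector& out_dims,
                                  bool nearest, double fill) {
  check_dims(dims); check_dims(out_dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (vol.size() != (R_xlen_t)nx * ny * nz) stop("volume size mismatch");
  if (M.nrow() != 3 || M.ncol() != 4) stop("M must be 3x4");
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  R_xlen_t o = 0;
  for (int z = 0; z < oz; ++z) {
    for (int y = 0; y < oy; ++y) {
      for (int x = 0; x < ox; ++x, ++o) {
        const double sx = M(0,0)*x + M(0,1)*y + M(0,2)*z + M(0,3);
        const double sy = M(1,0)*x + M(1,1)*y + M(1,2)*z + M(1,3);
        const double sz = M(2,0)*x + M(2,1)*y + M(2,2)*z + M(2,3);
        if (nearest) {
          const int ix = (int)std::lround(sx);
          const int iy = (int)std::lround(sy);
          const int iz = (int)std::lround(sz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
            out[o] = fill;
          else
            out[o] = v[ix + nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          if (sx < 0 || sy < 0 || sz < 0 ||
              x0 > nx - 1 || y0 > ny - 1 || z0 > nz - 1) { out[o] = fill; continue; }
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int zi = z0 + dz;
            const double wz = dz ? fz : 1.0 - fz;
            if (zi < 0 || zi >= nz || wz == 0.0) { if (wz != 0.0) acc += wz * fill; continue; }
            for (int dy = 0; dy < 2; ++dy) {
              const int yi = y0 + dy;
              const double wy = dy ? fy : 1.0 - fy;
              if (yi < 0 || yi >= ny || wy == 0.0) { if (wy != 0.0) acc += wz * wy * fill; continue; }
              for (int dx = 0; dx < 2; ++dx) {
                const int xi = x0 + dx;
                const double wx = dx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                const double w = wz * wy * wx;
                if (xi < 0 || xi >= nx) acc += w * fill;
                else acc += w * v[xi + nx * (yi + (R_xlen_t)ny * zi)];
              }
            }
          }
          out[o] = acc;
        }
      }
    }
  }
  return out;
}

// Voxels of `mask` belonging to 26-connected components that contain at
// least one seed (1-based voxel triplets, rows of `seeds`).
// [[Rcpp::export]]
LogicalVector cpp_flood_select(const LogicalVector& mask,
                               const IntegerVector& dims,
                               const IntegerMatrix& seeds) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (mask.size() != N) stop("mask size mismatch");
  LogicalVector out(N);
  std::vector<char> seen(N, 0);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int x = seeds(s, 0) - 1, y = seeds(s, 1) - 1, z = seeds(s, 2) - 1;
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
      stop("seed %d lies outside the grid", s + 1);
    const R_xlen_t i = x + nx * (y + (R_xlen_t)ny * z);
    if (!mask[i]) stop("seed %d lies outside the mask", s + 1);
    if (!seen[i]) { seen[i] = 1; q.push(i); }
  }
  while (!q.empty()) {
    const R_xlen_t i = q.front(); q.pop();
    out[i] = true;
    const int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          const R_xlen_t j = xx + nx * (yy + (R_xlen_t)ny * zz);
          if (!seen[j] && mask[j]) { seen[j] = 1; q.push(j); }
        }
  }
  return out;
}

// ---- fused conv + batch-norm + ReLU -------------------------------------
// Direct-loop 3x3x3 convolution (no patch matrix): for each channel pair
// the input column stays cache-resident across the 27 offsets. Forward
// returns the post-ReLU map plus opaque float caches (input copy and
// normalized activations) reused by the backward pass.

static void conv3_direct_fw(const arma::fmat& X, int nx, int ny, int nz,
                            const arma::fmat& Wf, arma::fmat& Z) {
  const int Cin = X.n_cols, Cout = Z.n_cols;
  for (int co = 0; co < Cout; ++co) {
    float* zc = Z.colptr(co);
    for (int ci = 0; ci < Cin; ++ci) {
      const float* xc = X.colptr(ci);
      for (int oz = -1; oz <= 1; ++oz) {
        for (int oy = -1; oy <= 1; ++oy) {
          for (int ox = -1; ox <= 1; ++ox) {
            const int k = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
            const float w = Wf(ci * 27 + k, co);
            if (w == 0.0f) continue;
            const int z0 = std::max(0, -oz), z1 = nz - 1 - std::max(0, oz);
            const int y0 = std::max(0, -oy), y1 = ny - 1 - std::max(0, oy);
            const int x0 = std::max(0, -ox), x1 = nx - 1 - std::max(0, ox);
            const int off = ox + nx * (oy + ny * oz);
            const int len = x1 - x0 + 1;
            for (int z = z0; z <= z1; ++z) {
              for (int y = y0; y <= y1; ++y) {
                const int base = nx * (y + ny * z) + x0;
                const float* src = xc + base + off;
                float* d = zc + base;
                for (int x = 0; x < len; ++x) d[x] += w * src[x];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_cbr_fw(const NumericMatrix& X, const IntegerVector& dims,
                const NumericMatrix& W, const NumericVector& b,
                const NumericVector& gamma, const NumericVector& beta) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  if (X.nrow() != N) stop("X rows do not match dims");
  const int Cin = X.ncol(), Cout = W.ncol();
  if (W.nrow() != 27 * Cin) stop("W must have 27*Cin rows");
  Rcpp::XPtr<arma::fmat> Xf(new arma::fmat(arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(X.begin()), N, Cin, false))), true);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(W.begin()), W.nrow(), Cout, false));
  arma::fmat Z(N, Cout, arma::fill::zeros);
  conv3_direct_fw(*Xf, nx, ny, nz, Wf, Z);
  Rcpp::XPtr<arma::fmat> xhat(new arma::fmat(N, Cout), true);
  NumericMatrix Y(N, Cout);
  NumericVector inv(Cout);
  for (int c = 0; c < Cout; ++c) {
    float* z = Z.colptr(c);
    const float bc = (float)b[c];
    double mu = 0;
    for (int i = 0; i < N; ++i) { z[i] += bc; mu += z[i]; }
    mu /= N;
    double var = 0;
    for (int i = 0; i < N; ++i) { const double d = z[i] - mu; var += d * d; }
    var /= N;
    const float ivc = (float)(1.0 / std::sqrt(var + 1e-5));
    inv[c] = ivc;
    float* xh = xhat->colptr(c);
    const float g = (float)gamma[c], be = (float)beta[c];
    double* y = &Y(0, c);
    for (int i = 0; i < N; ++i) {
      xh[i] = (z[i] - (float)mu) * ivc;
      const float v = g * xh[i] + be;
      y[i] = v > 0.0f ? v : 0.0;
    }
  }
  return List::create(_["Y"] = Y, _["xin"] = Xf, _["xhat"] = xhat,
                      _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_cbr_bw(const NumericMatrix& dY, const NumericMatrix& Y,
                SEXP xinPtr, SEXP xhatPtr, const NumericVector& inv,
                const NumericVector& gamma, const NumericMatrix& W,
                const IntegerVector& dims, bool want_dx) {
  check_dims(dims);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  Rcpp::XPtr<arma::fmat> Xf(xinPtr);
  Rcpp::XPtr<arma::fmat> xhat(xhatPtr);
  const int Cout = dY.ncol();
  const int Cin = W.nrow() / 27;
  if ((int)xhat->n_rows != N || (int)xhat->n_cols != Cout ||
      (int)Xf->n_rows != N || (int)Xf->n_cols != Cin)
    stop("stale cache: shape mismatch");
  // ReLU mask and batch-norm backward, fused per channel
  arma::fmat dz(N, Cout);
  NumericVector dg(Cout), dbe(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* dy = &dY(0, c);
    const double* y = &Y(0, c);
    const float* xh = xhat->colptr(c);
    float* dzc = dz.colptr(c);
    double s_dxh = 0, s_dxh_xh = 0, s_dg = 0, s_db = 0;
    const float g = (float)gamma[c];
    for (int i = 0; i < N; ++i) {
      const float dyi = y[i] > 0.0 ? (float)dy[i] : 0.0f;
      s_dg += (double)dyi * xh[i];
      s_db += dyi;
      const float dxh = dyi * g;
      dzc[i] = dxh;
      s_dxh += dxh;
      s_dxh_xh += (double)dxh * xh[i];
    }
    dg[c] = s_dg; dbe[c] = s_db;
    const float m1 = (float)(s_dxh / N);
    const float m2 = (float)(s_dxh_xh / N);
    const float ivc = (float)inv[c];
    for (int i = 0; i < N; ++i)
      dzc[i] = (dzc[i] - m1 - xh[i] * m2) * ivc;
  }
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(W.begin()), W.nrow(), Cout, false));
  // weight gradient: correlation of dz with the cached input
  NumericMatrix dWo(27 * Cin, Cout);
  for (int co = 0; co < Cout; ++co) {
    const float* dzc = dz.colptr(co);
    for (int ci = 0; ci < Cin; ++ci) {
      const float* xc = Xf->colptr(ci);
      for (int oz = -1; oz <= 1; ++oz) {
        for (int oy = -1; oy <= 1; ++oy) {
          for (int ox = -1; ox <= 1; ++ox) {
            const int k = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
            const int z0 = std::max(0, -oz), z1 = nz - 1 - std::max(0, oz);
            const int y0 = std::max(0, -oy), y1 = ny - 1 - std::max(0, oy);
            const int x0 = std::max(0, -ox), x1 = nx - 1 - std::max(0, ox);
            const int off = ox + nx * (oy + ny * oz);
            const int len = x1 - x0 + 1;
            double s = 0;
            for (int z = z0; z <= z1; ++z) {
              for (int y = y0; y <= y1; ++y) {
                const int base = nx * (y + ny * z) + x0;
                const float* a = dzc + base;
                const float* bb = xc + base + off;
                float acc = 0.0f;
                for (int x = 0; x < len; ++x) acc += a[x] * bb[x];
                s += acc;
              }
            }
            dWo(ci * 27 + k, co) = s;
          }
        }
      }
    }
  }
  NumericVector dbo(Cout);
  for (int c = 0; c < Cout; ++c)
    dbo[c] = arma::accu(dz.col(c));
  List out;
  if (want_dx) {
    // input gradient: convolution of dz with the flipped kernel
    arma::fmat dX(N, Cin, arma::fill::zeros);
    for (int ci = 0; ci < Cin; ++ci) {
      float* dxc = dX.colptr(ci);
      for (int co = 0; co < Cout; ++co) {
        const float* dzc = dz.colptr(co);
        for (int oz = -1; oz <= 1; ++oz) {
          for (int oy = -1; oy <= 1; ++oy) {
            for (int ox = -1; ox <= 1; ++ox) {
              const int k = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
              const float w = Wf(ci * 27 + k, co);
              if (w == 0.0f) continue;
              const int z0 = std::max(0, -oz), z1 = nz - 1 - std::max(0, oz);
              const int y0 = std::max(0, -oy), y1 = ny - 1 - std::max(0, oy);
              const int x0 = std::max(0, -ox), x1 = nx - 1 - std::max(0, ox);
              const int off = ox + nx * (oy + ny * oz);
              const int len = x1 - x0 + 1;
              for (int z = z0; z <= z1; ++z) {
                for (int y = y0; y <= y1; ++y) {
                  const int base = nx * (y + ny * z) + x0;
                  const float* a = dzc + base;
                  float* d = dxc + base + off;
                  for (int x = 0; x < len; ++x) d[x] += w * a[x];
                }
              }
            }
          }
        }
      }
    }
    NumericMatrix dXo(N, Cin);
    std::copy(dX.begin(), dX.end(), dXo.begin());
    out = List::create(_["dX"] = dXo, _["dW"] = dWo, _["db"] = dbo,
                       _["dg"] = dg, _["dbe"] = dbe);
  } else {
    out = List::create(_["dW"] = dWo, _["db"] = dbo, _["dg"] = dg,
                       _["dbe"] = dbe);
  }
  return out;
}
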