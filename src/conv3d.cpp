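#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Feature maps are column-major double arrays of dim (nx, ny, nz, C);
// depthwise kernels are (K, K, K, C). 'Same' zero padding, odd K.

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() == 3) { d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2]; d[3] = 1; }
  else { d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2]; d[3] = dm[3]; }
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3(NumericVector x, NumericVector w, NumericVector bias) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int K = wd[0], r = (K - 1) / 2;
  if (wd[3] != C) stop("kernel channel count (%d) != input channels (%d)", wd[3], C);
  if (K % 2 == 0) stop("kernel edge must be odd");
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* X = x.begin();
  const double* W = w.begin();
  double* O = out.begin();
  const R_xlen_t csX = (R_xlen_t)nx * ny * nz;
  const int K2 = K * K;
  std::vector<double> acc(nx);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + csX * c;
    const double* Wc = W + (R_xlen_t)K * K2 * c;
    const double bc = bias[c];
    double* Oc = O + csX * c;
    for (int oz = 0; oz < nz; ++oz) {
      for (int oy = 0; oy < ny; ++oy) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int kz = 0; kz < K; ++kz) {
          const int iz = oz + kz - r;
          if (iz < 0 || iz >= nz) continue;
          for (int ky = 0; ky < K; ++ky) {
            const int iy = oy + ky - r;
            if (iy < 0 || iy >= ny) continue;
            const double* row = Xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
            const double* wrow = Wc + (R_xlen_t)K * (ky + (R_xlen_t)K * kz);
            for (int kx = 0; kx < K; ++kx) {
              const double wv = wrow[kx];
              if (wv == 0.0) continue;
              const int sh = kx - r;             // ix = ox + sh
              int lo = sh < 0 ? -sh : 0;
              int hi = sh > 0 ? nx - sh : nx;    // ox in [lo, hi)
              const double* rs = row + sh;
              for (int ox = lo; ox < hi; ++ox) acc[ox] += wv * rs[ox];
            }
          }
        }
        double* orow = Oc + (R_xlen_t)nx * (oy + (R_xlen_t)ny * oz);
        for (int ox = 0; ox < nx; ++ox) orow[ox] = acc[ox] + bc;
      }
    }
  }
  return out;
}

// Gradients of the depthwise conv wrt kernel and bias given upstream grad.
// (Gradient wrt the input is cpp_dwconv3 with the flipped kernel, done in R.)
// [[Rcpp::export]]
List cpp_dwconv3_grad(NumericVector x, NumericVector gout, IntegerVector kdim) {
  int xd[4];
  get_dims4(x, xd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int K = kdim[0], r = (K - 1) / 2;
  NumericVector gw((R_xlen_t)K * K * K * C), gb(C);
  gw.attr("dim") = IntegerVector::create(K, K, K, C);
  const double* X = x.begin();
  const double* G = gout.begin();
  double* GW = gw.begin();
  const R_xlen_t csX = (R_xlen_t)nx * ny * nz;
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + csX * c;
    const double* Gc = G + csX * c;
    double* GWc = GW + (R_xlen_t)K * K * K * c;
    double bsum = 0.0;
    for (int oz = 0; oz < nz; ++oz) {
      for (int oy = 0; oy < ny; ++oy) {
        const double* grow = Gc + (R_xlen_t)nx * (oy + (R_xlen_t)ny * oz);
        for (int ox = 0; ox < nx; ++ox) bsum += grow[ox];
        for (int kz = 0; kz < K; ++kz) {
          const int iz = oz + kz - r;
          if (iz < 0 || iz >= nz) continue;
          for (int ky = 0; ky < K; ++ky) {
            const int iy = oy + ky - r;
            if (iy < 0 || iy >= ny) continue;
            const double* row = Xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
            double* gwrow = GWc + (R_xlen_t)K * (ky + (R_xlen_t)K * kz);
            for (int kx = 0; kx < K; ++kx) {
              const int sh = kx - r;
              int lo = sh < 0 ? -sh : 0;
              int hi = sh > 0 ? nx - sh : nx;
              const double* rs = row + sh;
              double s = 0.0;
              for (int ox = lo; ox < hi; ++ox) s += grow[ox] * rs[ox];
              gwrow[kx] += s;
            }
          }
        }
      }
    }
    gb[c] = bsum;
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// Strided (stride 2) 2x2x2 depthwise convolution used for downsampling.
// [[Rcpp::export]]
NumericVector cpp_dwdown2(NumericVector x, NumericVector w, NumericVector bias) {
  int xd[4];
  get_dims4(x, xd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("downsample needs even edge lengths");
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector out((R_xlen_t)mx * my * mz * C);
  out.attr("dim") = IntegerVector::create(mx, my, mz, C);
  const double* X = x.begin(); const double* W = w.begin(); double* O = out.begin();
  const R_xlen_t csX = (R_xlen_t)nx * ny * nz, csO = (R_xlen_t)mx * my * mz;
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + csX * c; const double* Wc = W + 8 * c;
    double* Oc = O + csO * c; const double bc = bias[c];
    for (int oz = 0; oz < mz; ++oz)
      for (int oy = 0; oy < my; ++oy)
        for (int ox = 0; ox < mx; ++ox) {
          double s = bc;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy) {
              const double* row = Xc + (R_xlen_t)nx * ((2 * oy + dy) + (R_xlen_t)ny * (2 * oz + dz)) + 2 * ox;
              const double* wr = Wc + 2 * (dy + 2 * dz);
              s += wr[0] * row[0] + wr[1] * row[1];
            }
          Oc[ox + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz)] = s;
        }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwdown2_grad(NumericVector x, NumericVector w, NumericVector gout) {
  int xd[4];
  get_dims4(x, xd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector gx(x.size()), gw(8 * C), gb(C);
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = IntegerVector::create(2, 2, 2, C);
  const double* X = x.begin(); const double* W = w.begin(); const double* G = gout.begin();
  double* GX = gx.begin(); double* GW = gw.begin();
  const R_xlen_t csX = (R_xlen_t)nx * ny * nz, csO = (R_xlen_t)mx * my * mz;
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + csX * c; const double* Wc = W + 8 * c; const double* Gc = G + csO * c;
    double* GXc = GX + csX * c; double* GWc = GW + 8 * c;
    double bsum = 0.0;
    for (int oz = 0; oz < mz; ++oz)
      for (int oy = 0; oy < my; ++oy)
        for (int ox = 0; ox < mx; ++ox) {
          const double g = Gc[ox + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz)];
          bsum += g;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t ii = (2 * ox + dx) + (R_xlen_t)nx * ((2 * oy + dy) + (R_xlen_t)ny * (2 * oz + dz));
                const int wi = dx + 2 * (dy + 2 * dz);
                GXc[ii] += g * Wc[wi];
                GWc[wi] += g * Xc[ii];
              }
        }
    gb[c] = bsum;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Trilinear x2 upsampling (half-voxel aligned: output o samples input o/2 - 0.25,
// clamped at the edges); backward is the exact transpose.
static void up2_index(int n, std::vector<int>& i0, std::vector<int>& i1,
                      std::vector<double>& w0, std::vector<double>& w1) {
  int m = 2 * n;
  i0.resize(m); i1.resize(m); w0.resize(m); w1.resize(m);
  for (int o = 0; o < m; ++o) {
    double pos = 0.5 * o - 0.25;
    int lo = (int)std::floor(pos);
    double f = pos - lo;
    int a = lo < 0 ? 0 : (lo > n - 1 ? n - 1 : lo);
    int b = lo + 1 < 0 ? 0 : (lo + 1 > n - 1 ? n - 1 : lo + 1);
    i0[o] = a; i1[o] = b; w0[o] = 1.0 - f; w1[o] = f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  int xd[4];
  get_dims4(x, xd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  std::vector<int> ix0, ix1, iy0, iy1, iz0, iz1;
  std::vector<double> wx0, wx1, wy0, wy1, wz0, wz1;
  up2_index(nx, ix0, ix1, wx0, wx1);
  up2_index(ny, iy0, iy1, wy0, wy1);
  up2_index(nz, iz0, iz1, wz0, wz1);
  NumericVector out((R_xlen_t)mx * my * mz * C);
  out.attr("dim") = IntegerVector::create(mx, my, mz, C);
  const double* X = x.begin(); double* O = out.begin();
  const R_xlen_t csX = (R_xlen_t)nx * ny * nz, csO = (R_xlen_t)mx * my * mz;
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + csX * c; double* Oc = O + csO * c;
    for (int oz = 0; oz < mz; ++oz)
      for (int oy = 0; oy < my; ++oy) {
        const double* p00 = Xc + (R_xlen_t)nx * (iy0[oy] + (R_xlen_t)ny * iz0[oz]);
        const double* p10 = Xc + (R_xlen_t)nx * (iy1[oy] + (R_xlen_t)ny * iz0[oz]);
        const double* p01 = Xc + (R_xlen_t)nx * (iy0[oy] + (R_xlen_t)ny * iz1[oz]);
        const double* p11 = Xc + (R_xlen_t)nx * (iy1[oy] + (R_xlen_t)ny * iz1[oz]);
        const double a00 = wy0[oy] * wz0[oz], a10 = wy1[oy] * wz0[oz];
        const double a01 = wy0[oy] * wz1[oz], a11 = wy1[oy] * wz1[oz];
        double* orow = Oc + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz);
        for (int ox = 0; ox < mx; ++ox) {
          const int a = ix0[ox], b = ix1[ox];
          const double u = wx0[ox], v = wx1[ox];
          orow[ox] = u * (a00 * p00[a] + a10 * p10[a] + a01 * p01[a] + a11 * p11[a])
                   + v * (a00 * p00[b] + a10 * p10[b] + a01 * p01[b] + a11 * p11[b]);
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_grad(NumericVector gout, IntegerVector in_dim) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], C = in_dim[3];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  std::vector<int> ix0, ix1, iy0, iy1, iz0, iz1;
  std::vector<double> wx0, wx1, wy0, wy1, wz0, wz1;
  up2_index(nx, ix0, ix1, wx0, wx1);
  up2_index(ny, iy0, iy1, wy0, wy1);
  up2_index(nz, iz0, iz1, wz0, wz1);
  NumericVector gx((R_xlen_t)nx * ny * nz * C);
  gx.attr("dim") = in_dim;
  const double* G = gout.begin(); double* GX = gx.begin();
  const R_xlen_t csX = (R_xlen_t)nx * ny * nz, csO = (R_xlen_t)mx * my * mz;
  for (int c = 0; c < C; ++c) {
    const double* Gc = G + csO * c; double* GXc = GX + csX * c;
    for (int oz = 0; oz < mz; ++oz)
      for (int oy = 0; oy < my; ++oy) {
        double* p00 = GXc + (R_xlen_t)nx * (iy0[oy] + (R_xlen_t)ny * iz0[oz]);
        double* p10 = GXc + (R_xlen_t)nx * (iy1[oy] + (R_xlen_t)ny * iz0[oz]);
        double* p01 = GXc + (R_xlen_t)nx * (iy0[oy] + (R_xlen_t)ny * iz1[oz]);
        double* p11 = GXc + (R_xlen_t)nx * (iy1[oy] + (R_xlen_t)ny * iz1[oz]);
        const double a00 = wy0[oy] * wz0[oz], a10 = wy1[oy] * wz0[oz];
        const double a01 = wy0[oy] * wz1[oz], a11 = wy1[oy] * wz1[oz];
        const double* grow = Gc + (R_xlen_t)mx * (oy + (R_xlen_t)my * oz);
        for (int ox = 0; ox < mx; ++ox) {
          const double g = grow[ox];
          const int a = ix0[ox], b = ix1[ox];
          const double u = wx0[ox] * g, v = wx1[ox] * g;
          p00[a] += u * a00; p10[a] += u * a10; p01[a] += u * a01; p11[a] += u * a11;
          p00[b] += v * a00; p10[b] += v * a10; p01[b] += v * a01; p11[b] += v * a11;
        }
      }
  }
  return gx;
}
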