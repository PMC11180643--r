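#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline interpolation with IIR prefiltering (mirror boundaries).
// The prefilter turns samples into spline coefficients so that evaluation
// at grid knots reproduces the samples exactly (interpolating spline).

static const double POLE = -0.26794919243112270647; // sqrt(3) - 2

static double initial_causal(const double *c, int n, double z, double tol) {
  int horizon = n;
  if (tol > 0.0) horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
  if (horizon < n) {
    double zn = z, sum = c[0];
    for (int k = 1; k < horizon; k++) { sum += zn * c[k]; zn *= z; }
    return sum;
  }
  // exact expression for short signals (mirror period 2n-2)
  double zn = z, iz = 1.0 / z;
  double z2n = std::pow(z, (double)(n - 1));
  double sum = c[0] + z2n * c[n - 1];
  z2n = z2n * z2n * iz;
  for (int k = 1; k <= n - 2; k++) {
    sum += (zn + z2n) * c[k];
    zn *= z;
    z2n *= iz;
  }
  return sum / (1.0 - std::pow(z, (double)(2 * n - 2)));
}

static void prefilter_line(double *c, int n) {
  if (n < 2) return;
  const double z = POLE;
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  for (int k = 0; k < n; k++) c[k] *= lambda;
  c[0] = initial_causal(c, n, z, 1e-14);
  for (int k = 1; k < n; k++) c[k] += z * c[k - 1];
  c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
  for (int k = n - 2; k >= 0; k--) c[k] = z * (c[k + 1] - c[k]);
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * (n - 1);
  i = i % p;
  if (i < 0) i += p;
  return (i < n) ? i : p - i;
}

static inline void bspline_weights(double t, int &i0, double w[4]) {
  i0 = (int)std::floor(t) - 1;
  double x = t - std::floor(t); // in [0,1)
  // weights for coefficients at i0 .. i0+3
  w[3] = x * x * x / 6.0;
  w[0] = 1.0 / 6.0 + x * (x - 1.0) / 2.0 - w[3];
  w[2] = x + w[0] - 2.0 * w[3];
  w[1] = 1.0 - w[0] - w[2] - w[3];
}

// [[Rcpp::export(name = ".cpp_bspline_prefilter")]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double *v = REAL(out);
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  // x lines
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      double *p = v + (size_t)nx * (j + (size_t)ny * k);
      prefilter_line(p, nx);
    }
  // y lines
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      for (int j = 0; j < ny; j++) line[j] = v[i + (size_t)nx * (j + (size_t)ny * k)];
      prefilter_line(line.data(), ny);
      for (int j = 0; j < ny; j++) v[i + (size_t)nx * (j + (size_t)ny * k)] = line[j];
    }
  // z lines
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      for (int k = 0; k < nz; k++) line[k] = v[i + (size_t)nx * (j + (size_t)ny * k)];
      prefilter_line(line.data(), nz);
      for (int k = 0; k < nz; k++) v[i + (size_t)nx * (j + (size_t)ny * k)] = line[k];
    }
  return out;
}

// Evaluate the cubic spline defined by coefficients `coef` at continuous
// input-grid indices t = (offset + i*step)/1, per axis; t is clamped to the
// grid so out-of-grid samples take the nearest edge value.
// [[Rcpp::export(name = ".cpp_bspline_sample")]]
NumericVector cpp_bspline_sample(NumericVector coef, IntegerVector dim,
                                 IntegerVector out_dim,
                                 NumericVector offset, NumericVector step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  const double *c = REAL(coef);
  NumericVector res((size_t)mx * my * mz);
  double *r = REAL(res);

  std::vector<int> ix0(mx), iy0(my), iz0(mz);
  std::vector<double> wx(4 * (size_t)mx), wy(4 * (size_t)my), wz(4 * (size_t)mz);
  for (int i = 0; i < mx; i++) {
    double t = offset[0] + i * step[0];
    t = std::min(std::max(t, 0.0), (double)(nx - 1));
    bspline_weights(t, ix0[i], &wx[4 * (size_t)i]);
  }
  for (int j = 0; j < my; j++) {
    double t = offset[1] + j * step[1];
    t = std::min(std::max(t, 0.0), (double)(ny - 1));
    bspline_weights(t, iy0[j], &wy[4 * (size_t)j]);
  }
  for (int k = 0; k < mz; k++) {
    double t = offset[2] + k * step[2];
    t = std::min(std::max(t, 0.0), (double)(nz - 1));
    bspline_weights(t, iz0[k], &wz[4 * (size_t)k]);
  }

  for (int k = 0; k < mz; k++) {
    int kz[4];
    for (int m = 0; m < 4; m++) kz[m] = mirror_idx(iz0[k] + m, nz);
    for (int j = 0; j < my; j++) {
      int jy[4];
      for (int m = 0; m < 4; m++) jy[m] = mirror_idx(iy0[j] + m, ny);
      for (int i = 0; i < mx; i++) {
        int ii[4];
        for (int m = 0; m < 4; m++) ii[m] = mirror_idx(ix0[i] + m, nx);
        double acc = 0.0;
        for (int mk = 0; mk < 4; mk++) {
          double accj = 0.0;
          const size_t base_k = (size_t)ny * kz[mk];
          for (int mj = 0; mj < 4; mj++) {
            const size_t base = (size_t)nx * (jy[mj] + base_k);
            double acci = c[ii[0] + base] * wx[4 * (size_t)i + 0] +
                          c[ii[1] + base] * wx[4 * (size_t)i + 1] +
                          c[ii[2] + base] * wx[4 * (size_t)i + 2] +
                          c[ii[3] + base] * wx[4 * (size_t)i + 3];
            accj += acci * wy[4 * (size_t)j + mj];
          }
          acc += accj * wz[4 * (size_t)k + mk];
        }
        r[i + (size_t)mx * (j + (size_t)my * k)] = acc;
      }
    }
  }
  return res;
}

// Nearest-neighbour sampling (masks): index = round(t), clamped to grid.
// [[Rcpp::export(name = ".cpp_nn_sample")]]
IntegerVector cpp_nn_sample(IntegerVector vol, IntegerVector dim,
                            IntegerVector out_dim,
                            NumericVector offset, NumericVector step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  const int *v = INTEGER(vol);
  IntegerVector res((size_t)mx * my * mz);
  int *r = INTEGER(res);
  std::vector<int> ix(mx), iy(my), iz(mz);
  for (int i = 0; i < mx; i++) {
    int t = (int)std::lround(offset[0] + i * step[0]);
    ix[i] = std::min(std::max(t, 0), nx - 1);
  }
  for (int j = 0; j < my; j++) {
    int t = (int)std::lround(offset[1] + j * step[1]);
    iy[j] = std::min(std::max(t, 0), ny - 1);
  }
  for (int k = 0; k < mz; k++) {
    int t = (int)std::lround(offset[2] + k * step[2]);
    iz[k] = std::min(std::max(t, 0), nz - 1);
  }
  for (int k = 0; k < mz; k++)
    for (int j = 0; j < my; j++)
      for (int i = 0; i < mx; i++)
        r[i + (size_t)mx * (j + (size_t)my * k)] =
            v[ix[i] + (size_t)nx * (iy[j] + (size_t)ny * iz[k])];
  return res;
}
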