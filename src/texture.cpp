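#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// bins: integer array, 0 outside ROI, 1..nbins inside (column-major, x fastest)

// 13 unique 3-D offsets at Chebyshev distance 1 (26-connectivity halved by
// point symmetry); lexicographic positive half.
static const int OFFS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0},
  {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export(name = ".cpp_offsets13")]]
IntegerMatrix cpp_offsets13() {
  IntegerMatrix m(13, 3);
  for (int d = 0; d < 13; d++)
    for (int a = 0; a < 3; a++) m(d, a) = OFFS[d][a];
  return m;
}

// Symmetric co-occurrence counts, one nbins x nbins slab per offset.
// [[Rcpp::export(name = ".cpp_glcm_counts")]]
NumericVector cpp_glcm_counts(IntegerVector bins, IntegerVector dim, int nbins) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *b = INTEGER(bins);
  NumericVector out((size_t)nbins * nbins * 13);
  double *o = REAL(out);
  for (int d = 0; d < 13; d++) {
    const int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    double *slab = o + (size_t)nbins * nbins * d;
    for (int k = 0; k < nz; k++) {
      int k2 = k + dz; if (k2 < 0 || k2 >= nz) continue;
      for (int j = 0; j < ny; j++) {
        int j2 = j + dy; if (j2 < 0 || j2 >= ny) continue;
        for (int i = 0; i < nx; i++) {
          int i2 = i + dx; if (i2 < 0 || i2 >= nx) continue;
          int a = b[i + (size_t)nx * (j + (size_t)ny * k)];
          if (a == 0) continue;
          int c = b[i2 + (size_t)nx * (j2 + (size_t)ny * k2)];
          if (c == 0) continue;
          slab[(a - 1) + (size_t)nbins * (c - 1)] += 1.0;
          slab[(c - 1) + (size_t)nbins * (a - 1)] += 1.0;
        }
      }
    }
  }
  return out;
}

// Run-length counts: nbins x maxlen slab per direction. Out-of-ROI voxels
// break runs; each maximal run is counted once (at its start voxel).
// [[Rcpp::export(name = ".cpp_glrlm_counts")]]
NumericVector cpp_glrlm_counts(IntegerVector bins, IntegerVector dim, int nbins) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *b = INTEGER(bins);
  const int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out((size_t)nbins * maxlen * 13);
  double *o = REAL(out);
  for (int d = 0; d < 13; d++) {
    const int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    double *slab = o + (size_t)nbins * maxlen * d;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int g = b[i + (size_t)nx * (j + (size_t)ny * k)];
          if (g == 0) continue;
          // run starts here iff predecessor is out of grid/ROI or differs
          int ip = i - dx, jp = j - dy, kp = k - dz;
          if (ip >= 0 && ip < nx && jp >= 0 && jp < ny && kp >= 0 && kp < nz) {
            if (b[ip + (size_t)nx * (jp + (size_t)ny * kp)] == g) continue;
          }
          int len = 1;
          int in = i + dx, jn = j + dy, kn = k + dz;
          while (in >= 0 && in < nx && jn >= 0 && jn < ny && kn >= 0 && kn < nz &&
                 b[in + (size_t)nx * (jn + (size_t)ny * kn)] == g) {
            len++; in += dx; jn += dy; kn += dz;
          }
          slab[(g - 1) + (size_t)nbins * (len - 1)] += 1.0;
        }
  }
  return out;
}

// 26-connected zones of equal bin value; returns one (level, size) row per zone.
// [[Rcpp::export(name = ".cpp_glszm_zones")]]
IntegerMatrix cpp_glszm_zones(IntegerVector bins, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *b = INTEGER(bins);
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> levels, sizes, stack;
  for (size_t s = 0; s < n; s++) {
    if (seen[s] || b[s] == 0) continue;
    const int g = b[s];
    int count = 0;
    stack.clear();
    stack.push_back((int)s);
    seen[s] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      count++;
      int ci = cur % nx, rem = cur / nx;
      int cj = rem % ny, ck = rem / ny;
      for (int dk = -1; dk <= 1; dk++) {
        int k2 = ck + dk; if (k2 < 0 || k2 >= nz) continue;
        for (int dj = -1; dj <= 1; dj++) {
          int j2 = cj + dj; if (j2 < 0 || j2 >= ny) continue;
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = ci + di; if (i2 < 0 || i2 >= nx) continue;
            size_t idx = i2 + (size_t)nx * (j2 + (size_t)ny * k2);
            if (!seen[idx] && b[idx] == g) { seen[idx] = 1; stack.push_back((int)idx); }
          }
        }
      }
    }
    levels.push_back(g);
    sizes.push_back(count);
  }
  IntegerMatrix out((int)levels.size(), 2);
  for (int z = 0; z < (int)levels.size(); z++) { out(z, 0) = levels[z]; out(z, 1) = sizes[z]; }
  return out;
}

// NGTDM accumulation: per gray level, voxel count n_i among valid voxels and
// s_i = sum |i - mean(in-ROI 26-neighbours)|. require_full = TRUE restricts
// valid voxels to those whose entire 26-neighbourhood lies inside the ROI.
// [[Rcpp::export(name = ".cpp_ngtdm")]]
List cpp_ngtdm(IntegerVector bins, IntegerVector dim, int nbins, bool require_full) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *b = INTEGER(bins);
  NumericVector ni(nbins), si(nbins);
  double nvalid = 0.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int g = b[i + (size_t)nx * (j + (size_t)ny * k)];
        if (g == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; dk++) {
          int k2 = k + dk; if (k2 < 0 || k2 >= nz) continue;
          for (int dj = -1; dj <= 1; dj++) {
            int j2 = j + dj; if (j2 < 0 || j2 >= ny) continue;
            for (int di = -1; di <= 1; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di; if (i2 < 0 || i2 >= nx) continue;
              int gn = b[i2 + (size_t)nx * (j2 + (size_t)ny * k2)];
              if (gn > 0) { sum += gn; cnt++; }
            }
          }
        }
        bool valid = require_full ? (cnt == 26) : (cnt >= 1);
        if (!valid) continue;
        nvalid += 1.0;
        ni[g - 1] += 1.0;
        si[g - 1] += std::fabs((double)g - sum / cnt);
      }
  return List::create(_["n_i"] = ni, _["s_i"] = si, _["n_valid"] = nvalid);
}
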