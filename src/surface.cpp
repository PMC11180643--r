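#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shape kernels on binary masks (0/1, column-major, x fastest).

static inline int mval(const int *m, int i, int j, int k, int nx, int ny, int nz) {
  if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0;
  return m[i + (size_t)nx * (j + (size_t)ny * k)];
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Triangulated 0.5-isosurface area via marching tetrahedra: each grid cell is
// split into the 6 Kuhn tetrahedra; binary corner values put iso-crossings at
// edge midpoints. Cells range one beyond the grid so the surface is closed.
// [[Rcpp::export(name = ".cpp_mesh_area")]]
double cpp_mesh_area(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *m = INTEGER(mask);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  // Kuhn decomposition: for each permutation of axes, tet = {000, e1, e1+e2, 111}
  static const int PERM[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
  };
  double area = 0.0;
  double P[4][3]; // tet corner positions (mm)
  int V[4];       // tet corner values

  for (int k = -1; k < nz; k++)
    for (int j = -1; j < ny; j++)
      for (int i = -1; i < nx; i++) {
        // corner values of the cell (i..i+1, j..j+1, k..k+1)
        int cv[2][2][2];
        int inside = 0;
        for (int a = 0; a < 2; a++)
          for (int b = 0; b < 2; b++)
            for (int c = 0; c < 2; c++) {
              cv[a][b][c] = mval(m, i + a, j + b, k + c, nx, ny, nz);
              inside += cv[a][b][c];
            }
        if (inside == 0 || inside == 8) continue;
        for (int t = 0; t < 6; t++) {
          int step[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
          step[1][PERM[t][0]] = 1;
          step[2][PERM[t][0]] = 1;
          step[2][PERM[t][1]] = 1;
          for (int v = 0; v < 4; v++) {
            V[v] = cv[step[v][0]][step[v][1]][step[v][2]];
            P[v][0] = (i + step[v][0]) * sx;
            P[v][1] = (j + step[v][1]) * sy;
            P[v][2] = (k + step[v][2]) * sz;
          }
          int cnt = V[0] + V[1] + V[2] + V[3];
          if (cnt == 0 || cnt == 4) continue;
          int in[4], out[4], ni = 0, no = 0;
          for (int v = 0; v < 4; v++) (V[v] ? in[ni++] : out[no++]) = v;
          double mid[4][3];
          if (cnt == 1 || cnt == 3) {
            int apex = (cnt == 1) ? in[0] : out[0];
            int others[3], w = 0;
            for (int v = 0; v < 4; v++) if (v != apex) others[w++] = v;
            for (int e = 0; e < 3; e++)
              for (int a = 0; a < 3; a++)
                mid[e][a] = 0.5 * (P[apex][a] + P[others[e]][a]);
            area += tri_area(mid[0], mid[1], mid[2]);
          } else { // 2 in, 2 out: quad across the four mixed edges
            int pairs[4][2] = {
              {in[0], out[0]}, {in[0], out[1]}, {in[1], out[1]}, {in[1], out[0]}
            };
            for (int e = 0; e < 4; e++)
              for (int a = 0; a < 3; a++)
                mid[e][a] = 0.5 * (P[pairs[e][0]][a] + P[pairs[e][1]][a]);
            area += tri_area(mid[0], mid[1], mid[2]);
            area += tri_area(mid[0], mid[2], mid[3]);
          }
        }
      }
  return area;
}

// Exposed-face surface area: every mask voxel face whose 6-neighbour is
// background (or outside the grid) contributes the face's physical area.
// [[Rcpp::export(name = ".cpp_voxel_face_area")]]
double cpp_voxel_face_area(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *m = INTEGER(mask);
  const double ax = spacing[1] * spacing[2];
  const double ay = spacing[0] * spacing[2];
  const double az = spacing[0] * spacing[1];
  double area = 0.0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (!m[i + (size_t)nx * (j + (size_t)ny * k)]) continue;
        if (!mval(m, i - 1, j, k, nx, ny, nz)) area += ax;
        if (!mval(m, i + 1, j, k, nx, ny, nz)) area += ax;
        if (!mval(m, i, j - 1, k, nx, ny, nz)) area += ay;
        if (!mval(m, i, j + 1, k, nx, ny, nz)) area += ay;
        if (!mval(m, i, j, k - 1, nx, ny, nz)) area += az;
        if (!mval(m, i, j, k + 1, nx, ny, nz)) area += az;
      }
  return area;
}

// Maximum Euclidean distance (mm) between centres of surface voxels
// (mask voxels with at least one background/out-of-grid 6-neighbour).
// [[Rcpp::export(name = ".cpp_max_diameter")]]
double cpp_max_diameter(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *m = INTEGER(mask);
  std::vector<double> px, py, pz;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (!m[i + (size_t)nx * (j + (size_t)ny * k)]) continue;
        if (mval(m, i - 1, j, k, nx, ny, nz) && mval(m, i + 1, j, k, nx, ny, nz) &&
            mval(m, i, j - 1, k, nx, ny, nz) && mval(m, i, j + 1, k, nx, ny, nz) &&
            mval(m, i, j, k - 1, nx, ny, nz) && mval(m, i, j, k + 1, nx, ny, nz))
          continue;
        px.push_back(i * spacing[0]);
        py.push_back(j * spacing[1]);
        pz.push_back(k * spacing[2]);
      }
  double best = 0.0;
  const size_t n = px.size();
  for (size_t a = 0; a < n; a++)
    for (size_t b = a + 1; b < n; b++) {
      double dx = px[a] - px[b], dy = py[a] - py[b], dz = pz[a] - pz[b];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
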