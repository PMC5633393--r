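#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- 1D squared distance transform (lower envelope of parabolas) ----------
static void dt1d(std::vector<double>& f, int n,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (f[v[k]] == INF) { // previous vertex unusable
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; goto placed; }
        --k;
        continue;
      }
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
    placed:;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - (double)v[kk];
    d[q] = (f[v[kk]] == INF) ? INF : dq * dq + f[v[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean distance (in voxel units) from every voxel to the nearest
// TRUE voxel of `mask`.  Voxels inside the target set get distance 0.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x lines
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, nx, v, z, d);
      for (int i = 0; i < nx; ++i) D[base + i] = f[i];
    }
  // y lines
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = D[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, ny, v, z, d);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = f[j];
    }
  // z lines
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = D[base + (R_xlen_t)k * plane]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, nz, v, z, d);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * plane] = f[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) D[i] = (D[i] == INF) ? INF : std::sqrt(D[i]);
  return D;
}

// Connected-component labels of TRUE voxels; 0 elsewhere.
// connectivity: 6 (face) or 26 (face+edge+vertex).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int k = (int)(p / plane);
      int rem = (int)(p % plane);
      int j = rem / nx, i = rem % nx;
      for (size_t m = 0; m < dxs.size(); ++m) {
        int ii = i + dxs[m], jj = j + dys[m], kk = k + dzs[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t q = (R_xlen_t)kk * plane + (R_xlen_t)jj * nx + ii;
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

static inline double triArea(const double a[3], const double b[3], const double c[3]) {
  double u0 = b[0] - a[0], u1 = b[1] - a[1], u2 = b[2] - a[2];
  double v0 = c[0] - a[0], v1 = c[1] - a[1], v2 = c[2] - a[2];
  double cx = u1 * v2 - u2 * v1;
  double cy = u2 * v0 - u0 * v2;
  double cz = u0 * v1 - u1 * v0;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Total area (voxel^2 units) of the iso-level surface of a scalar field,
// by marching tetrahedra (six tetrahedra per cell, linear interpolation).
// [[Rcpp::export]]
double mt_surface_area_cpp(NumericVector field, IntegerVector dim, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t plane = (R_xlen_t)nx * ny;
  // six tetrahedra sharing the 0-7 diagonal; cube corner c = bits (x,y,z)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  double area = 0.0;
  double corner[8][3];
  double fv[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyBelow = false, anyAbove = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          double val = field[(R_xlen_t)kk * plane + (R_xlen_t)jj * nx + ii];
          fv[c] = val;
          corner[c][0] = ii; corner[c][1] = jj; corner[c][2] = kk;
          if (val < iso) anyBelow = true; else anyAbove = true;
        }
        if (!anyBelow || !anyAbove) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int below[4], above[4];
          int nb = 0, na = 0;
          for (int m = 0; m < 4; ++m) {
            if (fv[idx[m]] < iso) below[nb++] = idx[m]; else above[na++] = idx[m];
          }
          if (nb == 0 || nb == 4) continue;
          double p[4][3];
          int np = 0;
          if (nb == 1 || nb == 3) {
            int apex = (nb == 1) ? below[0] : above[0];
            int* oth = (nb == 1) ? above : below;
            for (int m = 0; m < 3; ++m) {
              double fa = fv[apex], fb = fv[oth[m]];
              double tt = (iso - fa) / (fb - fa);
              for (int d = 0; d < 3; ++d)
                p[np][d] = corner[apex][d] + tt * (corner[oth[m]][d] - corner[apex][d]);
              ++np;
            }
            area += triArea(p[0], p[1], p[2]);
          } else { // 2-2: quad
            int pairs[4][2] = {{below[0], above[0]}, {below[0], above[1]},
                               {below[1], above[1]}, {below[1], above[0]}};
            for (int m = 0; m < 4; ++m) {
              double fa = fv[pairs[m][0]], fb = fv[pairs[m][1]];
              double tt = (iso - fa) / (fb - fa);
              for (int d = 0; d < 3; ++d)
                p[np][d] = corner[pairs[m][0]][d] +
                           tt * (corner[pairs[m][1]][d] - corner[pairs[m][0]][d]);
              ++np;
            }
            area += triArea(p[0], p[1], p[2]) + triArea(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}
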