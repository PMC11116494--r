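#pragma once
#include <Rcpp.h>
#include <cmath>

// Lightweight view onto an R-side potential/mobility grid (list with
// values / dim / origin / spacing).  Values are stored in R array order:
// first index fastest.
struct GridView {
  const double *v;
  int nx, ny, nz;
  double ox, oy, oz, dx, dy, dz;
};

inline GridView grid_view(const Rcpp::List &g) {
  Rcpp::NumericVector vals = g["values"];
  Rcpp::IntegerVector dim = g["dim"];
  Rcpp::NumericVector o = g["origin"], s = g["spacing"];
  GridView gv;
  gv.v = vals.begin();
  gv.nx = dim[0]; gv.ny = dim[1]; gv.nz = dim[2];
  gv.ox = o[0]; gv.oy = o[1]; gv.oz = o[2];
  gv.dx = s[0]; gv.dy = s[1]; gv.dz = s[2];
  return gv;
}

inline double gval(const GridView &g, int i, int j, int k) {
  if (i < 0) i = 0; else if (i >= g.nx) i = g.nx - 1;
  if (j < 0) j = 0; else if (j >= g.ny) j = g.ny - 1;
  if (k < 0) k = 0; else if (k >= g.nz) k = g.nz - 1;
  return g.v[(size_t)i + (size_t)g.nx * ((size_t)j + (size_t)g.ny * k)];
}

// Force = -scale * grad(values) at (x,y,z).  Node gradients (central
// differences) are interpolated trilinearly so the force field is continuous
// across voxel boundaries.  Positions outside the grid are clamped.
inline void grid_force_at(const GridView &g, double x, double y, double z,
                          double scale, double *f) {
  double fx = (x - g.ox) / g.dx, fy = (y - g.oy) / g.dy, fz = (z - g.oz) / g.dz;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  double tx = fx - i, ty = fy - j, tz = fz - k;
  if (i < 0) { i = 0; tx = 0.0; } else if (i > g.nx - 2) { i = g.nx - 2; tx = 1.0; }
  if (j < 0) { j = 0; ty = 0.0; } else if (j > g.ny - 2) { j = g.ny - 2; ty = 1.0; }
  if (k < 0) { k = 0; tz = 0.0; } else if (k > g.nz - 2) { k = g.nz - 2; tz = 1.0; }
  double gx = 0.0, gy = 0.0, gz = 0.0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        double w = (a ? tx : 1.0 - tx) * (b ? ty : 1.0 - ty) * (c ? tz : 1.0 - tz);
        if (w == 0.0) continue;
        int ii = i + a, jj = j + b, kk = k + c;
        gx += w * (gval(g, ii + 1, jj, kk) - gval(g, ii - 1, jj, kk)) / (2.0 * g.dx);
        gy += w * (gval(g, ii, jj + 1, kk) - gval(g, ii, jj - 1, kk)) / (2.0 * g.dy);
        gz += w * (gval(g, ii, jj, kk + 1) - gval(g, ii, jj, kk - 1)) / (2.0 * g.dz);
      }
  f[0] -= scale * gx;
  f[1] -= scale * gy;
  f[2] -= scale * gz;
}

// Trilinear interpolation of the grid values themselves.
inline double grid_value_at(const GridView &g, double x, double y, double z) {
  double fx = (x - g.ox) / g.dx, fy = (y - g.oy) / g.dy, fz = (z - g.oz) / g.dz;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  double tx = fx - i, ty = fy - j, tz = fz - k;
  if (i < 0) { i = 0; tx = 0.0; } else if (i > g.nx - 2) { i = g.nx - 2; tx = 1.0; }
  if (j < 0) { j = 0; ty = 0.0; } else if (j > g.ny - 2) { j = g.ny - 2; ty = 1.0; }
  if (k < 0) { k = 0; tz = 0.0; } else if (k > g.nz - 2) { k = g.nz - 2; tz = 1.0; }
  double out = 0.0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        double w = (a ? tx : 1.0 - tx) * (b ? ty : 1.0 - ty) * (c ? tz : 1.0 - tz);
        if (w == 0.0) continue;
        out += w * gval(g, i + a, j + b, k + c);
      }
  return out;
}
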