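#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "grid.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (separable lower-envelope
// algorithm, Felzenszwalb & Huttenlocher).  Coordinates are index * spacing,
// so anisotropic voxels are handled.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double> &f, std::vector<double> &out, int n,
                 double d, std::vector<int> &v, std::vector<double> &zb) {
  const double INF = 1e30;
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double d2 = d * d;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q * d2) - (f[p] + p * (double)p * d2)) /
          (2.0 * d2 * (q - p));
      if (s <= zb[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < (double)q) ++k;
    double dq = (q - v[k]) * d;
    out[q] = dq * dq + f[v[k]];
  }
}

// Squared distance (length^2) from every voxel to the nearest voxel where
// `fluid` is TRUE.  Fluid voxels get 0.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fluid, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e30;
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> d(n);
  for (size_t idx = 0; idx < n; ++idx) d[idx] = fluid[idx] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, out, nx, spacing[0], v, zb);
      for (int i = 0; i < nx; ++i) d[base + i] = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * ny * (size_t)k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (size_t)nx * j];
      dt1d(f, out, ny, spacing[1], v, zb);
      for (int j = 0; j < ny; ++j) d[base + (size_t)nx * j] = out[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * j;
      size_t stride = (size_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = d[base + stride * k];
      dt1d(f, out, nz, spacing[2], v, zb);
      for (int k = 0; k < nz; ++k) d[base + stride * k] = out[k];
    }

  NumericVector res(n);
  for (size_t idx = 0; idx < n; ++idx) res[idx] = d[idx];
  return res;
}

// ---------------------------------------------------------------------------
// Convolution of a penalty field with a normalised radial ramp kernel.
// Out-of-grid source voxels contribute `oob_value` (the domain boundary is
// treated as wall).
// ---------------------------------------------------------------------------

struct KOff { int di, dj, dk; double w; };

static std::vector<KOff> ramp_offsets(const NumericVector &spacing,
                                      double inner, double outer,
                                      bool decreasing) {
  std::vector<KOff> off;
  int ri = (int)std::ceil(outer / spacing[0]);
  int rj = (int)std::ceil(outer / spacing[1]);
  int rk = (int)std::ceil(outer / spacing[2]);
  double wsum = 0.0;
  for (int dk = -rk; dk <= rk; ++dk)
    for (int dj = -rj; dj <= rj; ++dj)
      for (int di = -ri; di <= ri; ++di) {
        double r = std::sqrt(di * spacing[0] * di * spacing[0] +
                             dj * spacing[1] * dj * spacing[1] +
                             dk * spacing[2] * dk * spacing[2]);
        if (r > outer) continue;
        double w;
        if (r <= inner) w = decreasing ? 1.0 : 0.0;
        else w = decreasing ? (outer - r) / (outer - inner)
                            : (r - inner) / (outer - inner);
        if (w <= 0.0) continue;
        off.push_back({di, dj, dk, w});
        wsum += w;
      }
    for (auto &o : off) o.w /= wsum;
  return off;
}

// [[Rcpp::export]]
DataFrame ramp_kernel_cpp(NumericVector spacing, double inner, double outer,
                          bool decreasing) {
  std::vector<KOff> off = ramp_offsets(spacing, inner, outer, decreasing);
  int n = off.size();
  IntegerVector di(n), dj(n), dk(n);
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    di[i] = off[i].di; dj[i] = off[i].dj; dk[i] = off[i].dk; w[i] = off[i].w;
  }
  return DataFrame::create(_["di"] = di, _["dj"] = dj, _["dk"] = dk, _["w"] = w);
}

// [[Rcpp::export]]
NumericVector convolve_ramp_cpp(NumericVector src, IntegerVector dim,
                                NumericVector spacing, double inner,
                                double outer, bool decreasing,
                                double oob_value) {
  std::vector<KOff> off = ramp_offsets(spacing, inner, outer, decreasing);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector res((size_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (const auto &o : off) {
          int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
          double s;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            s = oob_value;
          else
            s = src[(size_t)ii + (size_t)nx * (jj + (size_t)ny * kk)];
          acc += o.w * s;
        }
        res[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = acc;
      }
  return res;
}

// ---------------------------------------------------------------------------
// R-facing interpolation helpers.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix grid_force_cpp(List grid, NumericMatrix pos, NumericVector scale) {
  GridView g = grid_view(grid);
  int n = pos.nrow();
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) {
    double fi[3] = {0.0, 0.0, 0.0};
    grid_force_at(g, pos(i, 0), pos(i, 1), pos(i, 2), scale[i % scale.size()], fi);
    f(i, 0) = fi[0]; f(i, 1) = fi[1]; f(i, 2) = fi[2];
  }
  return f;
}

// [[Rcpp::export]]
NumericVector grid_value_cpp(List grid, NumericMatrix pos) {
  GridView g = grid_view(grid);
  int n = pos.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = grid_value_at(g, pos(i, 0), pos(i, 1), pos(i, 2));
  return out;
}
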