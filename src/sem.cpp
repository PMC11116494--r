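#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "grid.h"
using namespace Rcpp;

// Steric-exclusion-model machinery: per-voxel relative ionic mobility
// factors.  factor = wall_mask * dna_factor(dist to nearest DNA bead)
//                 * crowder_ramp(dist to nearest crowder centre).
// The DNA factor is an enhancement profile (> 1 near the bead, 1 in bulk);
// the crowder ramp is 0 below `crw_inner`, 1 above `crw_outer`, linear
// in between.

// stamp min squared distances from particles onto voxels within `rad`
static void stamp_min_d2(std::vector<double> &d2, const GridView &g,
                         const double *px, const double *py, const double *pz,
                         int np, int stride, double rad) {
  double rad2 = rad * rad;
  for (int p = 0; p < np; ++p) {
    double X = px[p * stride], Y = py[p * stride], Z = pz[p * stride];
    int i0 = (int)std::floor((X - rad - g.ox) / g.dx);
    int i1 = (int)std::ceil((X + rad - g.ox) / g.dx);
    int j0 = (int)std::floor((Y - rad - g.oy) / g.dy);
    int j1 = (int)std::ceil((Y + rad - g.oy) / g.dy);
    int k0 = (int)std::floor((Z - rad - g.oz) / g.dz);
    int k1 = (int)std::ceil((Z + rad - g.oz) / g.dz);
    if (i0 < 0) i0 = 0; if (i1 > g.nx - 1) i1 = g.nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > g.ny - 1) j1 = g.ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > g.nz - 1) k1 = g.nz - 1;
    for (int k = k0; k <= k1; ++k) {
      double dz = g.oz + k * g.dz - Z;
      for (int j = j0; j <= j1; ++j) {
        double dy = g.oy + j * g.dy - Y;
        for (int i = i0; i <= i1; ++i) {
          double dx = g.ox + i * g.dx - X;
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > rad2) continue;
          size_t idx = (size_t)i + (size_t)g.nx * (j + (size_t)g.ny * k);
          if (r2 < d2[idx]) d2[idx] = r2;
        }
      }
    }
  }
}

static inline double dna_factor(double d2, double f0, double r_in, double r_out) {
  if (d2 >= r_out * r_out) return 1.0;
  double d = std::sqrt(d2);
  if (d <= r_in) return f0;
  return f0 + (1.0 - f0) * (d - r_in) / (r_out - r_in);
}

static inline double crw_ramp(double d2, double inner, double outer) {
  if (d2 >= outer * outer) return 1.0;
  double d = std::sqrt(d2);
  if (d <= inner) return 0.0;
  return (d - inner) / (outer - inner);
}

// [[Rcpp::export]]
NumericVector sem_factor_cpp(List base_grid, NumericMatrix dna_pos,
                             NumericMatrix crw_pos, double f0, double dna_rin,
                             double dna_rout, double crw_inner,
                             double crw_outer) {
  GridView g = grid_view(base_grid);
  size_t nv = (size_t)g.nx * g.ny * g.nz;
  const double INF = 1e30;
  std::vector<double> d2d(nv, INF), d2c(nv, INF);
  if (dna_pos.nrow() > 0)
    stamp_min_d2(d2d, g, &dna_pos(0, 0), &dna_pos(0, 1), &dna_pos(0, 2),
                 dna_pos.nrow(), 1, dna_rout);
  if (crw_pos.nrow() > 0)
    stamp_min_d2(d2c, g, &crw_pos(0, 0), &crw_pos(0, 1), &crw_pos(0, 2),
                 crw_pos.nrow(), 1, crw_outer);
  NumericVector out(nv);
  for (size_t idx = 0; idx < nv; ++idx)
    out[idx] = g.v[idx] * dna_factor(d2d[idx], f0, dna_rin, dna_rout) *
               crw_ramp(d2c[idx], crw_inner, crw_outer);
  return out;
}

// Slab-series current (pA) from a factor grid: per-axial-slab conductance
// G_k = sigma * sum_k(factor) * dx*dy / dz ; I = bias / sum(1/G_k).
// Returns NA if any slab has zero conductance (blocked pore).
static double slab_current(const double *fac, const GridView &g, double bias_mV,
                           double sigma_Sm) {
  double rsum = 0.0;
  for (int k = 0; k < g.nz; ++k) {
    double s = 0.0;
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        s += fac[(size_t)i + (size_t)g.nx * (j + (size_t)g.ny * k)];
    if (s <= 0.0) return NA_REAL;
    double gk = sigma_Sm * 1e-9 * s * g.dx * g.dy / g.dz; // siemens
    rsum += 1.0 / gk;
  }
  return bias_mV / rsum * 1e9 * 1e-3 * 1e12 / 1e9; // mV/ohm -> pA
}

// [[Rcpp::export]]
double slab_current_cpp(List grid, double bias_mV, double sigma_Sm) {
  GridView g = grid_view(grid);
  return slab_current(g.v, g, bias_mV, sigma_Sm);
}

// Current time series over trajectory frames (n x 3 x nf array).
// [[Rcpp::export]]
NumericVector sem_trace_cpp(List base_grid, NumericVector frames, int n_dna,
                            int n_total, double f0, double dna_rin,
                            double dna_rout, double crw_inner, double crw_outer,
                            double bias_mV, double sigma_Sm) {
  GridView g = grid_view(base_grid);
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  if (n != n_total) stop("frame particle count mismatch");
  size_t nv = (size_t)g.nx * g.ny * g.nz;
  const double INF = 1e30;
  std::vector<double> d2d(nv), d2c(nv), fac(nv);
  NumericVector out(nf);
  const double *fr = frames.begin();
  int n_crw = n_total - n_dna;
  for (int t = 0; t < nf; ++t) {
    const double *X = fr + (size_t)t * n * 3;
    const double *Y = X + n;
    const double *Z = Y + n;
    std::fill(d2d.begin(), d2d.end(), INF);
    std::fill(d2c.begin(), d2c.end(), INF);
    if (n_dna > 0) {
      // columns of the frame are contiguous x, y, z blocks
      std::vector<double> px(n_dna), py(n_dna), pz(n_dna);
      for (int i = 0; i < n_dna; ++i) { px[i] = X[i]; py[i] = Y[i]; pz[i] = Z[i]; }
      stamp_min_d2(d2d, g, px.data(), py.data(), pz.data(), n_dna, 1, dna_rout);
    }
    if (n_crw > 0) {
      std::vector<double> px(n_crw), py(n_crw), pz(n_crw);
      for (int i = 0; i < n_crw; ++i) {
        px[i] = X[n_dna + i]; py[i] = Y[n_dna + i]; pz[i] = Z[n_dna + i];
      }
      stamp_min_d2(d2c, g, px.data(), py.data(), pz.data(), n_crw, 1, crw_outer);
    }
    for (size_t idx = 0; idx < nv; ++idx)
      fac[idx] = g.v[idx] * dna_factor(d2d[idx], f0, dna_rin, dna_rout) *
                 crw_ramp(d2c[idx], crw_inner, crw_outer);
    out[t] = slab_current(fac.data(), g, bias_mV, sigma_Sm);
  }
  return out;
}
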