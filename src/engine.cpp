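#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "grid.h"
using namespace Rcpp;

// Overdamped Brownian dynamics of DNA beads (species 0, indices < n_dna) and
// crowders (species 1).  Forces: voxel grids (steric per species,
// electrostatic on charged beads), bonded chain terms, and pairwise 12-6 LJ
// in Rmin/eps form with a Verlet neighbour list.
//
// Update rule per coordinate: x += (D/kT) F dt + sqrt(2 D dt) xi,
// xi ~ N(0,1) from R's RNG stream (seeded on the R side).

struct PairPar {
  double rmin2, eps, cut2, rcap2;
  bool rep_only, active;
};

// Fast deterministic normal generator for the thermal noise: splitmix64
// uniforms + Box-Muller, seeded from R's RNG stream so set.seed() on the R
// side fixes the whole trajectory.
struct FastRng {
  uint64_t s;
  bool has_spare = false;
  double spare = 0.0;
  explicit FastRng(uint64_t seed) : s(seed) {}
  inline uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  inline double unif() { // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// Precomputed node gradients of a grid (central differences, clamped at the
// boundary), trilinearly interpolated at force time.  Identical arithmetic
// to grid_force_at, amortised over the run.
struct GradGrid {
  std::vector<double> gr; // interleaved (gx, gy, gz) per voxel
  GridView g;
  void build(const GridView &gv) {
    g = gv;
    size_t nvox = (size_t)g.nx * g.ny * g.nz;
    gr.resize(3 * nvox);
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          size_t idx = (size_t)i + (size_t)g.nx * (j + (size_t)g.ny * k);
          gr[3 * idx] = (gval(g, i + 1, j, k) - gval(g, i - 1, j, k)) / (2.0 * g.dx);
          gr[3 * idx + 1] = (gval(g, i, j + 1, k) - gval(g, i, j - 1, k)) / (2.0 * g.dy);
          gr[3 * idx + 2] = (gval(g, i, j, k + 1) - gval(g, i, j, k - 1)) / (2.0 * g.dz);
        }
  }
  inline void force(double x, double y, double z, double scale, double *f) const {
    double fx = (x - g.ox) / g.dx, fy = (y - g.oy) / g.dy, fz = (z - g.oz) / g.dz;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    double tx = fx - i, ty = fy - j, tz = fz - k;
    if (i < 0) { i = 0; tx = 0.0; } else if (i > g.nx - 2) { i = g.nx - 2; tx = 1.0; }
    if (j < 0) { j = 0; ty = 0.0; } else if (j > g.ny - 2) { j = g.ny - 2; ty = 1.0; }
    if (k < 0) { k = 0; tz = 0.0; } else if (k > g.nz - 2) { k = g.nz - 2; tz = 1.0; }
    double ax = 0.0, ay = 0.0, az = 0.0;
    const double wx[2] = {1.0 - tx, tx}, wy[2] = {1.0 - ty, ty},
                 wz[2] = {1.0 - tz, tz};
    for (int c = 0; c < 2; ++c)
      for (int b = 0; b < 2; ++b) {
        double wbc = wy[b] * wz[c];
        if (wbc == 0.0) continue;
        size_t row = (size_t)i + (size_t)g.nx * ((j + b) + (size_t)g.ny * (k + c));
        for (int a = 0; a < 2; ++a) {
          double w = wx[a] * wbc;
          if (w == 0.0) continue;
          const double *p = &gr[3 * (row + a)];
          ax += w * p[0];
          ay += w * p[1];
          az += w * p[2];
        }
      }
    f[0] -= scale * ax;
    f[1] -= scale * ay;
    f[2] -= scale * az;
  }
};

static inline void lj_accum(const PairPar &pp, double dx, double dy, double dz,
                            double r2, double *fi, double *fj) {
  if (!pp.active || r2 >= pp.cut2) return;
  if (pp.rep_only && r2 >= pp.rmin2) return;
  double r2e = r2 < pp.rcap2 ? pp.rcap2 : r2; // force cap at tiny separations
  double s2 = pp.rmin2 / r2e;
  double s6 = s2 * s2 * s2;
  double fr = 12.0 * pp.eps * (s6 * s6 - s6) / r2e; // >0 repulsive
  fi[0] -= fr * dx; fi[1] -= fr * dy; fi[2] -= fr * dz;
  fj[0] += fr * dx; fj[1] += fr * dy; fj[2] += fr * dz;
}

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix pos0, int n_dna,
                List grid_dna, List grid_crw, List grid_elec, bool use_elec,
                NumericVector elec_scale, // per particle: q_e * (kcal/mol per e.mV)
                NumericVector Dcoef,      // nm^2/ns per particle
                double k_bond, double r0, double k_bend,
                NumericMatrix pair_rmin, NumericMatrix pair_eps,
                NumericMatrix pair_cut, LogicalMatrix pair_rep,
                double dt, double kT, double nsteps_d, int frame_every,
                bool record_crossings, double post_eject_ns,
                double warn_disp, int check_every, double skin,
                bool forces_only) {
  RNGScope scope;
  const int n = pos0.nrow();
  const long nsteps = (long)nsteps_d;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2); }

  GradGrid gd, gc, ge;
  if (n_dna > 0) gd.build(grid_view(grid_dna));
  if (n > n_dna) gc.build(grid_view(grid_crw));
  if (use_elec && n_dna > 0) ge.build(grid_view(grid_elec));
  FastRng rng(((uint64_t)(R::unif_rand() * 4294967296.0) << 32) ^
              (uint64_t)(R::unif_rand() * 4294967296.0));

  PairPar pp[2][2];
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) {
      double rm = pair_rmin(a, b);
      pp[a][b].rmin2 = rm * rm;
      pp[a][b].eps = pair_eps(a, b);
      pp[a][b].cut2 = pair_cut(a, b) * pair_cut(a, b);
      pp[a][b].rcap2 = 0.36 * rm * rm; // cap below 0.6 Rmin
      pp[a][b].rep_only = pair_rep(a, b);
      pp[a][b].active = pair_eps(a, b) > 0.0;
    }
  double max_cut = 0.0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      if (pp[a][b].active) max_cut = std::max(max_cut, pair_cut(a, b));
  const double list_cut2 = (max_cut + skin) * (max_cut + skin);

  std::vector<int> nbr_i, nbr_j;
  std::vector<double> x0(n), y0(n), z0(n); // positions at last list build
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> mu(n), noise(n);
  for (int i = 0; i < n; ++i) {
    mu[i] = Dcoef[i] / kT * dt;
    noise[i] = std::sqrt(2.0 * Dcoef[i] * dt);
  }

  auto build_list = [&]() {
    nbr_i.clear(); nbr_j.clear();
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (i < n_dna && j < n_dna && j - i <= 2) continue; // bonded exclusions
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        if (dx * dx + dy * dy + dz * dz < list_cut2) {
          nbr_i.push_back(i);
          nbr_j.push_back(j);
        }
      }
      x0[i] = x[i]; y0[i] = y[i]; z0[i] = z[i];
    }
  };
  build_list();

  auto compute_forces = [&]() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // grid forces
    for (int i = 0; i < n; ++i) {
      double fi[3] = {0.0, 0.0, 0.0};
      if (i < n_dna) {
        gd.force(x[i], y[i], z[i], 1.0, fi);
        if (use_elec && elec_scale[i] != 0.0)
          ge.force(x[i], y[i], z[i], elec_scale[i], fi);
      } else {
        gc.force(x[i], y[i], z[i], 1.0, fi);
      }
      fx[i] += fi[0]; fy[i] += fi[1]; fz[i] += fi[2];
    }
    // bonds
    for (int i = 0; i + 1 < n_dna; ++i) {
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double fmag = -k_bond * (r - r0) / r;
      fx[i + 1] += fmag * dx; fy[i + 1] += fmag * dy; fz[i + 1] += fmag * dz;
      fx[i] -= fmag * dx; fy[i] -= fmag * dy; fz[i] -= fmag * dz;
    }
    // angles
    for (int i = 0; i + 2 < n_dna; ++i) {
      double r1x = x[i + 1] - x[i], r1y = y[i + 1] - y[i], r1z = z[i + 1] - z[i];
      double r2x = x[i + 2] - x[i + 1], r2y = y[i + 2] - y[i + 1], r2z = z[i + 2] - z[i + 1];
      double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
      double g1x = r2x / (n1 * n2) - c * r1x / (n1 * n1);
      double g1y = r2y / (n1 * n2) - c * r1y / (n1 * n1);
      double g1z = r2z / (n1 * n2) - c * r1z / (n1 * n1);
      double g2x = r1x / (n1 * n2) - c * r2x / (n2 * n2);
      double g2y = r1y / (n1 * n2) - c * r2y / (n2 * n2);
      double g2z = r1z / (n1 * n2) - c * r2z / (n2 * n2);
      double fax = -k_bend * g1x, fay = -k_bend * g1y, faz = -k_bend * g1z;
      double fcx = k_bend * g2x, fcy = k_bend * g2y, fcz = k_bend * g2z;
      fx[i] += fax; fy[i] += fay; fz[i] += faz;
      fx[i + 2] += fcx; fy[i + 2] += fcy; fz[i + 2] += fcz;
      fx[i + 1] -= fax + fcx; fy[i + 1] -= fay + fcy; fz[i + 1] -= faz + fcz;
    }
    // pairs
    for (size_t p = 0; p < nbr_i.size(); ++p) {
      int i = nbr_i[p], j = nbr_j[p];
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      const PairPar &par = pp[i < n_dna ? 0 : 1][j < n_dna ? 0 : 1];
      double fi[3] = {0, 0, 0}, fj[3] = {0, 0, 0};
      lj_accum(par, dx, dy, dz, r2, fi, fj);
      fx[i] += fi[0]; fy[i] += fi[1]; fz[i] += fi[2];
      fx[j] += fj[0]; fy[j] += fj[1]; fz[j] += fj[2];
    }
  };

  if (forces_only) {
    compute_forces();
    NumericMatrix fout(n, 3);
    for (int i = 0; i < n; ++i) {
      fout(i, 0) = fx[i]; fout(i, 1) = fy[i]; fout(i, 2) = fz[i];
    }
    return List::create(_["forces"] = fout);
  }

  // frame storage
  std::vector<double> frames;
  std::vector<double> ftimes;
  auto save_frame = [&](double t) {
    for (int i = 0; i < n; ++i) frames.push_back(x[i]);
    for (int i = 0; i < n; ++i) frames.push_back(y[i]);
    for (int i = 0; i < n; ++i) frames.push_back(z[i]);
    ftimes.push_back(t);
  };
  save_frame(0.0);

  std::vector<double> cross(n_dna, NA_REAL);
  int n_crossed = 0;
  bool ejected = false;
  double eject_time = NA_REAL;
  long warn_count = 0;
  const double warn2 = warn_disp * warn_disp;
  const double half_skin2 = 0.25 * skin * skin;
  long step = 0;
  bool done = false;

  for (step = 1; step <= nsteps && !done; ++step) {
    compute_forces();
    double maxmove2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double zprev = z[i];
      double ddx = mu[i] * fx[i] + noise[i] * rng.normal();
      double ddy = mu[i] * fy[i] + noise[i] * rng.normal();
      double ddz = mu[i] * fz[i] + noise[i] * rng.normal();
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > warn2) ++warn_count;
      if (record_crossings && i < n_dna && ISNA(cross[i]) && z[i] < 0.0) {
        double frac = zprev > 0.0 ? zprev / (zprev - z[i]) : 0.0;
        cross[i] = (step - 1) * dt + frac * dt;
        ++n_crossed;
      }
      double sx = x[i] - x0[i], sy = y[i] - y0[i], sz = z[i] - z0[i];
      double m2 = sx * sx + sy * sy + sz * sz;
      if (m2 > maxmove2) maxmove2 = m2;
    }
    if (maxmove2 > half_skin2) build_list();
    if (step % frame_every == 0) save_frame(step * dt);
    if (record_crossings && !ejected && n_crossed == n_dna &&
        step % check_every == 0) {
      bool all_below = true;
      for (int i = 0; i < n_dna; ++i)
        if (z[i] >= 0.0) { all_below = false; break; }
      if (all_below) {
        ejected = true;
        eject_time = step * dt;
      }
    }
    if (ejected && (step * dt - eject_time) >= post_eject_ns) done = true;
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  long last_step = step - 1; // last executed step (loop increments past it)
  if (ftimes.back() < last_step * dt) save_frame(last_step * dt);

  int nf = ftimes.size();
  NumericVector fr(frames.size());
  std::copy(frames.begin(), frames.end(), fr.begin());
  fr.attr("dim") = IntegerVector::create(n, 3, nf);
  NumericMatrix pos_final(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_final(i, 0) = x[i]; pos_final(i, 1) = y[i]; pos_final(i, 2) = z[i];
  }
  return List::create(
      _["frames"] = fr, _["times"] = NumericVector(ftimes.begin(), ftimes.end()),
      _["crossing_ns"] = NumericVector(cross.begin(), cross.end()),
      _["ejected"] = ejected, _["eject_time"] = eject_time,
      _["steps_run"] = (double)last_step,
      _["warn_frac"] = n > 0 ? (double)warn_count / ((double)last_step * n) : 0.0,
      _["positions"] = pos_final);
}
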