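#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bonded + excluded-volume mechanics of the bead-spring chain.
//  bonds : E = 1/2 k_bond (r - r0)^2 between consecutive beads
//  angles: E = k_bend (1 - cos phi), phi the angle between consecutive bond
//          vectors (discrete worm-like chain)
//  self  : purely repulsive (Wendland-style truncated-and-shifted) 12-6 LJ in
//          Rmin/eps form, cut at Rmin, between beads separated by > 2 bonds
//
// Returns both the total energy and the analytic forces so the force field
// can be validated against a numerical gradient.

// [[Rcpp::export]]
List dna_internal_cpp(NumericMatrix pos, double k_bond, double r0,
                      double k_bend, double rmin_dd, double eps_dd) {
  const int n = pos.nrow();
  NumericMatrix f(n, 3);
  double energy = 0.0;

  // bonds
  for (int i = 0; i + 1 < n; ++i) {
    double dx = pos(i + 1, 0) - pos(i, 0);
    double dy = pos(i + 1, 1) - pos(i, 1);
    double dz = pos(i + 1, 2) - pos(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0;
    energy += 0.5 * k_bond * dr * dr;
    double fmag = -k_bond * dr / r; // force on i+1 along +d
    f(i + 1, 0) += fmag * dx; f(i + 1, 1) += fmag * dy; f(i + 1, 2) += fmag * dz;
    f(i, 0) -= fmag * dx; f(i, 1) -= fmag * dy; f(i, 2) -= fmag * dz;
  }

  // angles (1 - cos form)
  for (int i = 0; i + 2 < n; ++i) {
    double r1x = pos(i + 1, 0) - pos(i, 0);
    double r1y = pos(i + 1, 1) - pos(i, 1);
    double r1z = pos(i + 1, 2) - pos(i, 2);
    double r2x = pos(i + 2, 0) - pos(i + 1, 0);
    double r2y = pos(i + 2, 1) - pos(i + 1, 1);
    double r2z = pos(i + 2, 2) - pos(i + 1, 2);
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    double dot = r1x * r2x + r1y * r2y + r1z * r2z;
    double c = dot / (n1 * n2);
    energy += k_bend * (1.0 - c);
    // d(cos)/dr1 and d(cos)/dr2
    double g1x = r2x / (n1 * n2) - c * r1x / (n1 * n1);
    double g1y = r2y / (n1 * n2) - c * r1y / (n1 * n1);
    double g1z = r2z / (n1 * n2) - c * r1z / (n1 * n1);
    double g2x = r1x / (n1 * n2) - c * r2x / (n2 * n2);
    double g2y = r1y / (n1 * n2) - c * r2y / (n2 * n2);
    double g2z = r1z / (n1 * n2) - c * r2z / (n2 * n2);
    // E = k(1-c): F_a = -dE/da = -k g1 ; F_c = +k g2 ; F_b = -(F_a+F_c)
    double fax = -k_bend * g1x, fay = -k_bend * g1y, faz = -k_bend * g1z;
    double fcx = k_bend * g2x, fcy = k_bend * g2y, fcz = k_bend * g2z;
    f(i, 0) += fax; f(i, 1) += fay; f(i, 2) += faz;
    f(i + 2, 0) += fcx; f(i + 2, 1) += fcy; f(i + 2, 2) += fcz;
    f(i + 1, 0) -= fax + fcx; f(i + 1, 1) -= fay + fcy; f(i + 1, 2) -= faz + fcz;
  }

  // soft self-exclusion (repulsive-only LJ, shifted so E(rmin) = 0)
  if (eps_dd > 0.0 && rmin_dd > 0.0) {
    double cut2 = rmin_dd * rmin_dd;
    for (int i = 0; i < n; ++i)
      for (int j = i + 3; j < n; ++j) {
        double dx = pos(j, 0) - pos(i, 0);
        double dy = pos(j, 1) - pos(i, 1);
        double dz = pos(j, 2) - pos(i, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= cut2) continue;
        double s2 = cut2 / r2;
        double s6 = s2 * s2 * s2;
        energy += eps_dd * (s6 * s6 - 2.0 * s6) + eps_dd;
        double fr = 12.0 * eps_dd * (s6 * s6 - s6) / r2; // * vector(i->j) on j
        f(j, 0) += fr * dx; f(j, 1) += fr * dy; f(j, 2) += fr * dz;
        f(i, 0) -= fr * dx; f(i, 1) -= fr * dy; f(i, 2) -= fr * dz;
      }
  }

  return List::create(_["energy"] = energy, _["forces"] = f);
}

// Direct Boltzmann sampling of the discrete worm-like chain defined by the
// bending term alone: successive bond directions deflected by angles drawn
// from p(cos phi) ~ exp(alpha cos phi), azimuth uniform.  Gives exact
// equilibrium statistics of the ideal (phantom) chain; used as the
// closed-form cross-check route, independent of the dynamics engine.
// [[Rcpp::export]]
NumericVector sample_wlc_rg_cpp(int n_beads, double bond, double alpha,
                                int n_chains) {
  RNGScope scope;
  NumericVector rg(n_chains);
  std::vector<double> x(n_beads), y(n_beads), z(n_beads);
  for (int c = 0; c < n_chains; ++c) {
    double ux = 0.0, uy = 0.0, uz = 1.0;
    x[0] = y[0] = z[0] = 0.0;
    for (int i = 1; i < n_beads; ++i) {
      if (i > 1) {
        // inverse-CDF sample of cos(phi) on [-1, 1] under exp(alpha c)
        double u = R::unif_rand();
        double cphi;
        if (alpha > 1e-12) {
          // F(c) = (exp(alpha c) - exp(-alpha)) / (exp(alpha)-exp(-alpha))
          double ea = std::exp(-2.0 * alpha);
          cphi = 1.0 + std::log(u * (1.0 - ea) + ea) / alpha;
        } else {
          cphi = 2.0 * u - 1.0;
        }
        double sphi = std::sqrt(std::max(0.0, 1.0 - cphi * cphi));
        double psi = 2.0 * M_PI * R::unif_rand();
        // build orthonormal frame around u
        double ax = 0.0, ay = 0.0, az = 0.0;
        if (std::fabs(ux) < 0.9) ax = 1.0; else ay = 1.0;
        // e1 = normalize(a - (a.u) u)
        double adotu = ax * ux + ay * uy + az * uz;
        double e1x = ax - adotu * ux, e1y = ay - adotu * uy, e1z = az - adotu * uz;
        double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
        e1x /= n1; e1y /= n1; e1z /= n1;
        double e2x = uy * e1z - uz * e1y;
        double e2y = uz * e1x - ux * e1z;
        double e2z = ux * e1y - uy * e1x;
        double nx = cphi * ux + sphi * (std::cos(psi) * e1x + std::sin(psi) * e2x);
        double ny = cphi * uy + sphi * (std::cos(psi) * e1y + std::sin(psi) * e2y);
        double nz = cphi * uz + sphi * (std::cos(psi) * e1z + std::sin(psi) * e2z);
        double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
        ux = nx / nn; uy = ny / nn; uz = nz / nn;
      }
      x[i] = x[i - 1] + bond * ux;
      y[i] = y[i - 1] + bond * uy;
      z[i] = z[i - 1] + bond * uz;
    }
    double cx = 0.0, cy = 0.0, cz = 0.0;
    for (int i = 0; i < n_beads; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
    cx /= n_beads; cy /= n_beads; cz /= n_beads;
    double s = 0.0;
    for (int i = 0; i < n_beads; ++i) {
      double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
      s += dx * dx + dy * dy + dz * dz;
    }
    rg[c] = std::sqrt(s / n_beads);
  }
  return rg;
}
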