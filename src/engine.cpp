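// Compiled hot loops: exact Siddon voxel traversal for radiological path
// lengths, the divergent-beam exponential-attenuation dose engine, and the
// bounded gamma-index search with trilinear interpolation.
//
// Grid convention (matches the R side): 0-based voxel indices; the world
// position of voxel (i,j,k) is origin + (i,j,k) * spacing; voxel (i,j,k)
// occupies [origin + (idx - 0.5) * spacing, origin + (idx + 0.5) * spacing).

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Grid {
  int n[3];
  double sp[3];
  double b0[3]; // lower edge of voxel 0 per axis
};

static Grid make_grid(const IntegerVector& n, const NumericVector& spacing,
                      const NumericVector& origin) {
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = n[a];
    g.sp[a] = spacing[a];
    g.b0[a] = origin[a] - 0.5 * spacing[a];
  }
  return g;
}

// Radiological path length of the segment p0 -> p1 through `red`:
// sum over traversed voxels of geometric intersection length times voxel
// value. Portions of the segment outside the grid contribute zero.
static double rpl_segment(const double* red, const Grid& g,
                          const double* p0, const double* p1) {
  double d[3];
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    double lo = g.b0[a], hi = g.b0[a] + (double)g.n[a] * g.sp[a];
    if (d[a] == 0.0) {
      if (p0[a] <= lo || p0[a] >= hi) return 0.0;
    } else {
      double ta = (lo - p0[a]) / d[a];
      double tb = (hi - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return 0.0;
  const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L == 0.0) return 0.0;

  int idx[3], step[3];
  double tnext[3], tdelta[3];
  const double teps = (t1 - t0) * 1e-12;
  for (int a = 0; a < 3; ++a) {
    double x = p0[a] + (t0 + teps) * d[a];
    int i = (int)std::floor((x - g.b0[a]) / g.sp[a]);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
    if (d[a] > 0.0) {
      step[a] = 1;
      tnext[a] = (((double)(i + 1)) * g.sp[a] + g.b0[a] - p0[a]) / d[a];
      tdelta[a] = g.sp[a] / d[a];
    } else if (d[a] < 0.0) {
      step[a] = -1;
      tnext[a] = (((double)i) * g.sp[a] + g.b0[a] - p0[a]) / d[a];
      tdelta[a] = -g.sp[a] / d[a];
    } else {
      step[a] = 0;
      tnext[a] = R_PosInf;
      tdelta[a] = R_PosInf;
    }
  }

  const R_xlen_t nx = g.n[0], ny = g.n[1];
  double t = t0, acc = 0.0;
  while (t < t1) {
    double te = std::min(std::min(tnext[0], tnext[1]), tnext[2]);
    if (te > t1) te = t1;
    if (te > t)
      acc += (te - t) * red[idx[0] + nx * (idx[1] + ny * (R_xlen_t)idx[2])];
    t = te;
    if (t >= t1) break;
    bool out = false;
    for (int a = 0; a < 3; ++a) {
      if (tnext[a] <= te) {
        idx[a] += step[a];
        if (idx[a] < 0 || idx[a] >= g.n[a]) out = true;
        tnext[a] += tdelta[a];
      }
    }
    if (out) break;
  }
  return acc * L;
}

// [[Rcpp::export(rng = false)]]
double cpp_rpl(NumericVector red, IntegerVector n, NumericVector spacing,
               NumericVector origin, NumericVector p0, NumericVector p1) {
  Grid g = make_grid(n, spacing, origin);
  double a[3] = {p0[0], p0[1], p0[2]};
  double b[3] = {p1[0], p1[1], p1[2]};
  return rpl_segment(REAL(red), g, a, b);
}

// Dose at every body voxel:
//   D(v) = sum_b w_b * (dref_b / d_b(v))^2 * exp(-mu_b * RPL(src_b -> v)) * A_b(v)
// where d_b is the source distance and A_b a Gaussian-edged circular
// aperture evaluated at the voxel's off-axis distance scaled back to the
// reference distance. Voxels outside `body` receive zero.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_compute_dose(NumericVector red, IntegerVector n,
                               NumericVector spacing, NumericVector origin,
                               LogicalVector body, NumericMatrix src,
                               NumericMatrix aim, NumericVector weight,
                               NumericVector mu, NumericVector aperture,
                               NumericVector dref, double edge_sigma) {
  Grid g = make_grid(n, spacing, origin);
  const int nb = src.nrow();
  const double* redp = REAL(red);
  const int nx = g.n[0], nyv = g.n[1], nz = g.n[2];
  NumericVector dose(red.size());

  // unit beam axes
  std::vector<double> ux(nb), uy(nb), uz(nb);
  for (int b = 0; b < nb; ++b) {
    double dx = aim(b, 0) - src(b, 0);
    double dy = aim(b, 1) - src(b, 1);
    double dz = aim(b, 2) - src(b, 2);
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    ux[b] = dx / L; uy[b] = dy / L; uz[b] = dz / L;
  }

  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * g.sp[2];
    for (int j = 0; j < nyv; ++j) {
      double py = origin[1] + j * g.sp[1];
      for (int i = 0; i < nx; ++i, ++v) {
        if (!body[v]) continue;
        double px = origin[0] + i * g.sp[0];
        double acc = 0.0;
        double p1[3] = {px, py, pz};
        for (int b = 0; b < nb; ++b) {
          double wx = px - src(b, 0);
          double wy = py - src(b, 1);
          double wz = pz - src(b, 2);
          double along = wx * ux[b] + wy * uy[b] + wz * uz[b];
          if (along <= 0.0) continue;
          double d2 = wx * wx + wy * wy + wz * wz;
          double perp2 = d2 - along * along;
          double perp = perp2 > 0.0 ? std::sqrt(perp2) : 0.0;
          // project the off-axis distance back to the reference distance
          double r_ref = perp * dref[b] / along;
          double excess = r_ref - aperture[b];
          double T = 1.0;
          if (excess > 0.0) {
            T = std::exp(-excess * excess / (2.0 * edge_sigma * edge_sigma));
            if (T < 1e-6) continue; // outside the penumbra, skip ray trace
          }
          double p0[3] = {src(b, 0), src(b, 1), src(b, 2)};
          double rpl = rpl_segment(redp, g, p0, p1);
          acc += weight[b] * (dref[b] * dref[b] / d2) *
                 std::exp(-mu[b] * rpl) * T;
        }
        dose[v] = acc;
      }
    }
  }
  dose.attr("dim") = n;
  return dose;
}

// trilinear interpolation of `v` at world point p; false if p is outside
// the voxel-centre hull
static bool trilin(const double* v, const Grid& g, const double px,
                   const double py, const double pz, double* out) {
  double f[3] = {(px - (g.b0[0] + 0.5 * g.sp[0])) / g.sp[0],
                 (py - (g.b0[1] + 0.5 * g.sp[1])) / g.sp[1],
                 (pz - (g.b0[2] + 0.5 * g.sp[2])) / g.sp[2]};
  int i0[3];
  double w[3];
  for (int a = 0; a < 3; ++a) {
    if (f[a] < 0.0 || f[a] > (double)(g.n[a] - 1)) return false;
    i0[a] = (int)std::floor(f[a]);
    if (i0[a] > g.n[a] - 2) i0[a] = g.n[a] - 2;
    if (i0[a] < 0) i0[a] = 0;
    w[a] = f[a] - (double)i0[a];
  }
  const R_xlen_t nx = g.n[0], ny = g.n[1];
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double wt = (dx ? w[0] : 1.0 - w[0]) * (dy ? w[1] : 1.0 - w[1]) *
                    (dz ? w[2] : 1.0 - w[2]);
        if (wt == 0.0) continue;
        acc += wt * v[(i0[0] + dx) + nx * ((i0[1] + dy) + ny * (R_xlen_t)(i0[2] + dz))];
      }
  *out = acc;
  return true;
}

// Gamma index with bounded search: for each reference voxel above the dose
// cutoff, minimise sqrt((dD/denom)^2 + (dr/DTA)^2) over a sub-voxel search
// grid of step `step` within `search_radius`, interpolating the evaluated
// dose trilinearly. Offsets are visited in order of increasing distance so
// the search can stop as soon as the distance term alone exceeds the
// current best gamma.
// [[Rcpp::export(rng = false)]]
List cpp_gamma(NumericVector ref, NumericVector eval, IntegerVector n,
               NumericVector spacing, NumericVector origin, double dose_tol,
               double dta, bool local, double norm_dose, double cutoff_abs,
               double search_radius, double step) {
  Grid g = make_grid(n, spacing, origin);
  const double* refp = REAL(ref);
  const double* evp = REAL(eval);
  const int nx = g.n[0], nyv = g.n[1], nz = g.n[2];

  // search offsets sorted by distance
  const int m = (int)std::floor(search_radius / step + 1e-9);
  std::vector<std::array<double, 4>> offs; // r2, dx, dy, dz
  offs.reserve((size_t)(2 * m + 1) * (2 * m + 1) * (2 * m + 1));
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double dx = a * step, dy = b * step, dz = c * step;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= search_radius * search_radius + 1e-12)
          offs.push_back({r2, dx, dy, dz});
      }
  std::sort(offs.begin(), offs.end(),
            [](const std::array<double, 4>& x, const std::array<double, 4>& y) {
              return x[0] < y[0];
            });

  NumericVector gamma(ref.size(), NA_REAL);
  R_xlen_t n_eval = 0, n_pass = 0;
  const double dta2 = dta * dta;

  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * g.sp[2];
    for (int j = 0; j < nyv; ++j) {
      double py = origin[1] + j * g.sp[1];
      for (int i = 0; i < nx; ++i, ++v) {
        double dr = refp[v];
        if (!(dr > 0.0) || dr < cutoff_abs) continue;
        double px = origin[0] + i * g.sp[0];
        double denom = dose_tol * (local ? dr : norm_dose);
        double best = R_PosInf;
        for (size_t o = 0; o < offs.size(); ++o) {
          double dist_term = offs[o][0] / dta2;
          if (dist_term >= best) break;
          double ev;
          if (!trilin(evp, g, px + offs[o][1], py + offs[o][2],
                      pz + offs[o][3], &ev))
            continue;
          double dd = (ev - dr) / denom;
          double g2 = dd * dd + dist_term;
          if (g2 < best) best = g2;
        }
        double gam = std::sqrt(best);
        gamma[v] = gam;
        ++n_eval;
        if (gam <= 1.0) ++n_pass;
      }
    }
  }
  gamma.attr("dim") = n;
  return List::create(_["gamma"] = gamma, _["n_evaluated"] = (double)n_eval,
                      _["n_pass"] = (double)n_pass);
}
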