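// Core bead-spring engine: pair/bond/angle forces, virial stress, and a
// BAOAB Langevin integrator with an optionally tilted (Lees-Edwards) box.
// All quantities are in reduced LJ units (m = sigma = epsilon = kB = 1 by
// default); unit scaling happens on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <sstream>
using namespace Rcpp;

namespace {

struct Box {
  double L[3];
  double tilt;        // xy tilt: x-offset of the y box vector
  bool per[3];
  bool xwall;         // reflective walls on x (per[0] must be false)
  double xlo, xhi;
};

// minimum-image separation in a (possibly xy-tilted) periodic box
inline void min_image(const Box& b, double& dx, double& dy, double& dz) {
  if (b.per[2]) dz -= b.L[2] * std::nearbyint(dz / b.L[2]);
  if (b.per[1]) {
    double n = std::nearbyint(dy / b.L[1]);
    dy -= n * b.L[1];
    dx -= n * b.tilt;
  }
  if (b.per[0]) dx -= b.L[0] * std::nearbyint(dx / b.L[0]);
}

struct PairParams {
  int ntypes;
  std::vector<double> eps, sig, rc, lam; // ntypes*ntypes, lam<0 => plain LJ
  int style;        // 0 = LJ / Ashbaugh-Hatch, 1 = soft push-off
  bool shift_force; // force-shifted truncation (style 0, plain LJ only)
  double rc_max;
  inline int idx(int ti, int tj) const { return ti * ntypes + tj; }
};

// pair energy and f(r)/r with f = -dU/dr (positive = repulsive)
inline bool pair_ef(const PairParams& p, int ti, int tj, double r2,
                    double& u, double& fdivr) {
  int k = p.idx(ti, tj);
  double rc = p.rc[k];
  if (r2 >= rc * rc) return false;
  double eps = p.eps[k], sig = p.sig[k];
  if (eps == 0.0) return false;
  double r = std::sqrt(r2);
  if (p.style == 1) { // soft cosine push-off, amplitude in eps
    double a = M_PI / rc;
    u = eps * (1.0 + std::cos(a * r));
    fdivr = eps * a * std::sin(a * r) / r;
    return true;
  }
  double sr2 = sig * sig / r2, sr6 = sr2 * sr2 * sr2;
  double ulj = 4.0 * eps * sr6 * (sr6 - 1.0);
  double flj = 24.0 * eps * sr6 * (2.0 * sr6 - 1.0) / r; // -dU/dr
  double lam = p.lam[k];
  if (lam >= 0.0) { // Ashbaugh-Hatch lambda-scaled LJ (HPS family)
    double rmin = std::pow(2.0, 1.0 / 6.0) * sig;
    double src2 = sig * sig / (rc * rc), src6 = src2 * src2 * src2;
    double ushift = (rc > rmin) ? lam * 4.0 * eps * src6 * (src6 - 1.0) : 0.0;
    if (r <= rmin) { u = ulj + (1.0 - lam) * eps - ushift; fdivr = flj / r; }
    else           { u = lam * ulj - ushift;               fdivr = lam * flj / r; }
    return true;
  }
  if (p.shift_force) {
    double src2 = sig * sig / (rc * rc), src6 = src2 * src2 * src2;
    double urc = 4.0 * eps * src6 * (src6 - 1.0);
    double frc = 24.0 * eps * src6 * (2.0 * src6 - 1.0) / rc;
    // U(r) - U(rc) - (r - rc) U'(rc) with U'(rc) = -frc
    u = ulj - urc + (r - rc) * frc;
    fdivr = (flj - frc) / r;
  } else {
    u = ulj;
    fdivr = flj / r;
  }
  return true;
}

struct TopoParams {
  int nb;                       // bonds
  std::vector<int> b1, b2, btype; // btype 1 = FENE, 2 = harmonic
  std::vector<double> bk, br0;
  int na;                       // angles (j is the vertex)
  std::vector<int> ai, aj, ak;
  std::vector<double> angk, angt0;
};

struct ForceOut {
  std::vector<double> fx, fy, fz;
  double energy;
  double w[6]; // virial sum r_a F_b: xx yy zz xy xz yz
};

// Verlet neighbour list rebuilt from a cell list (O(N)); falls back to an
// O(N^2) sweep when the box is too small for 3 cells per axis.
struct NeighborList {
  std::vector<int> li, lj;
  std::vector<double> x0, y0, z0;
  double skin;
  bool built = false;

  void add_if_close(const Box& box, const std::vector<double>& x,
                    const std::vector<double>& y, const std::vector<double>& z,
                    int i, int j, double rl2) {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    min_image(box, dx, dy, dz);
    if (dx * dx + dy * dy + dz * dz < rl2) { li.push_back(i); lj.push_back(j); }
  }

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, const Box& box, double rc_max) {
    int n = (int)x.size();
    li.clear(); lj.clear();
    double rl = rc_max + skin, rl2 = rl * rl;
    // fractional-coordinate cell grid (handles the xy tilt)
    int nx = (int)std::floor(box.L[0] / (rl * 1.05));
    int ny = (int)std::floor(box.L[1] / (rl * 1.05));
    int nz = (int)std::floor(box.L[2] / (rl * 1.05));
    if (n < 200 || nx < 3 || ny < 3 || nz < 3) {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j)
          add_if_close(box, x, y, z, i, j, rl2);
    } else {
      int ncell = nx * ny * nz;
      std::vector<int> head(ncell, -1), next(n, -1), cell_of(n);
      auto wrapi = [](int k, int nk) { k %= nk; return k < 0 ? k + nk : k; };
      for (int i = 0; i < n; ++i) {
        double sy = y[i] / box.L[1];
        double sx = (x[i] - box.tilt * sy) / box.L[0];
        double sz = z[i] / box.L[2];
        int cx = wrapi((int)std::floor(sx * nx), nx);
        int cy = wrapi((int)std::floor(sy * ny), ny);
        int cz = wrapi((int)std::floor(sz * nz), nz);
        int c = (cz * ny + cy) * nx + cx;
        cell_of[i] = c;
        next[i] = head[c];
        head[c] = i;
      }
      for (int cz = 0; cz < nz; ++cz)
        for (int cy = 0; cy < ny; ++cy)
          for (int cx = 0; cx < nx; ++cx) {
            int c = (cz * ny + cy) * nx + cx;
            // same cell
            for (int i = head[c]; i >= 0; i = next[i])
              for (int j = next[i]; j >= 0; j = next[j])
                add_if_close(box, x, y, z, i, j, rl2);
            // half stencil of neighbour cells (c2 > c once per unordered pair)
            for (int oz = -1; oz <= 1; ++oz)
              for (int oy = -1; oy <= 1; ++oy)
                for (int ox = -1; ox <= 1; ++ox) {
                  if (ox == 0 && oy == 0 && oz == 0) continue;
                  int c2 = (wrapi(cz + oz, nz) * ny + wrapi(cy + oy, ny)) * nx +
                           wrapi(cx + ox, nx);
                  if (c2 <= c) continue;
                  for (int i = head[c]; i >= 0; i = next[i])
                    for (int j = head[c2]; j >= 0; j = next[j])
                      add_if_close(box, x, y, z, i, j, rl2);
                }
          }
    }
    x0 = x; y0 = y; z0 = z;
    built = true;
  }

  bool stale(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, const Box& box) const {
    if (!built) return true;
    double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < x.size(); ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      min_image(box, dx, dy, dz); // wraps are not real displacements
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

void compute_forces(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& z, const std::vector<int>& type,
                    const Box& box, const PairParams& pp, const TopoParams& tp,
                    const NeighborList& nl, ForceOut& out) {
  int n = (int)x.size();
  out.fx.assign(n, 0.0); out.fy.assign(n, 0.0); out.fz.assign(n, 0.0);
  out.energy = 0.0;
  for (int k = 0; k < 6; ++k) out.w[k] = 0.0;

  // nonbonded
  for (size_t p = 0; p < nl.li.size(); ++p) {
    int i = nl.li[p], j = nl.lj[p];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    min_image(box, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    double u, fdivr;
    if (!pair_ef(pp, type[i], type[j], r2, u, fdivr)) continue;
    out.energy += u;
    double fxp = fdivr * dx, fyp = fdivr * dy, fzp = fdivr * dz;
    out.fx[i] += fxp; out.fy[i] += fyp; out.fz[i] += fzp;
    out.fx[j] -= fxp; out.fy[j] -= fyp; out.fz[j] -= fzp;
    out.w[0] += dx * fxp; out.w[1] += dy * fyp; out.w[2] += dz * fzp;
    out.w[3] += dx * fyp; out.w[4] += dx * fzp; out.w[5] += dy * fzp;
  }

  // bonds
  for (int b = 0; b < tp.nb; ++b) {
    int i = tp.b1[b], j = tp.b2[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    min_image(box, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz, r = std::sqrt(r2);
    double u, fdivr;
    if (tp.btype[b] == 1) { // FENE
      double R0 = tp.br0[b], k = tp.bk[b];
      if (r >= R0) {
        std::ostringstream msg;
        msg << "FENE bond " << (b + 1) << " overstretched: r = " << r
            << " >= R0 = " << R0 << " (beads " << (i + 1) << ", " << (j + 1) << ")";
        stop(msg.str());
      }
      double q = 1.0 - r2 / (R0 * R0);
      u = -0.5 * k * R0 * R0 * std::log(q);
      fdivr = -k / q; // attractive
    } else { // harmonic: U = k (r - r0)^2
      double k = tp.bk[b], r0 = tp.br0[b];
      u = k * (r - r0) * (r - r0);
      fdivr = -2.0 * k * (r - r0) / r;
    }
    out.energy += u;
    double fxp = fdivr * dx, fyp = fdivr * dy, fzp = fdivr * dz;
    out.fx[i] += fxp; out.fy[i] += fyp; out.fz[i] += fzp;
    out.fx[j] -= fxp; out.fy[j] -= fyp; out.fz[j] -= fzp;
    out.w[0] += dx * fxp; out.w[1] += dy * fyp; out.w[2] += dz * fzp;
    out.w[3] += dx * fyp; out.w[4] += dx * fzp; out.w[5] += dy * fzp;
  }

  // angles: U = K (theta - theta0)^2, vertex j
  for (int a = 0; a < tp.na; ++a) {
    int i = tp.ai[a], j = tp.aj[a], k = tp.ak[a];
    double d1x = x[i] - x[j], d1y = y[i] - y[j], d1z = z[i] - z[j];
    double d2x = x[k] - x[j], d2y = y[k] - y[j], d2z = z[k] - z[j];
    min_image(box, d1x, d1y, d1z);
    min_image(box, d2x, d2y, d2z);
    double r1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
    double r2 = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
    if (r1 <= 0.0 || r2 <= 0.0) stop("degenerate angle: zero bond length");
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double theta = std::acos(c);
    double K = tp.angk[a], t0 = tp.angt0[a];
    out.energy += K * (theta - t0) * (theta - t0);
    double dUdtheta = 2.0 * K * (theta - t0);
    double aa = dUdtheta / s; // = -dU/dcos(theta)... chain rule sign folded below
    // dtheta/dr gives forces: F_i = -(aa) * (d2/(r1 r2) - c d1/r1^2), etc.
    double f1x = aa * (d2x / (r1 * r2) - c * d1x / (r1 * r1));
    double f1y = aa * (d2y / (r1 * r2) - c * d1y / (r1 * r1));
    double f1z = aa * (d2z / (r1 * r2) - c * d1z / (r1 * r1));
    double f3x = aa * (d1x / (r1 * r2) - c * d2x / (r2 * r2));
    double f3y = aa * (d1y / (r1 * r2) - c * d2y / (r2 * r2));
    double f3z = aa * (d1z / (r1 * r2) - c * d2z / (r2 * r2));
    out.fx[i] += f1x; out.fy[i] += f1y; out.fz[i] += f1z;
    out.fx[k] += f3x; out.fy[k] += f3y; out.fz[k] += f3z;
    out.fx[j] -= f1x + f3x; out.fy[j] -= f1y + f3y; out.fz[j] -= f1z + f3z;
    out.w[0] += d1x * f1x + d2x * f3x;
    out.w[1] += d1y * f1y + d2y * f3y;
    out.w[2] += d1z * f1z + d2z * f3z;
    out.w[3] += d1x * f1y + d2x * f3y;
    out.w[4] += d1x * f1z + d2x * f3z;
    out.w[5] += d1y * f1z + d2y * f3z;
  }

  // reflective-wall contribution carries no configurational virial here;
  // wall reflection is handled in the integrator.
}

Box unpack_box(List box) {
  Box b;
  NumericVector L = box["L"];
  b.L[0] = L[0]; b.L[1] = L[1]; b.L[2] = L[2];
  b.tilt = as<double>(box["tilt"]);
  LogicalVector per = box["periodic"];
  b.per[0] = per[0]; b.per[1] = per[1]; b.per[2] = per[2];
  b.xwall = false; b.xlo = 0.0; b.xhi = b.L[0];
  if (box.containsElementNamed("xwalls") && !Rf_isNull(box["xwalls"])) {
    NumericVector w = box["xwalls"];
    b.xwall = true; b.xlo = w[0]; b.xhi = w[1];
  }
  return b;
}

PairParams unpack_pairs(List pair) {
  PairParams p;
  NumericMatrix eps = pair["eps"], sig = pair["sigma"], rc = pair["rc"],
                lam = pair["lambda"];
  p.ntypes = eps.nrow();
  int nn = p.ntypes * p.ntypes;
  p.eps.resize(nn); p.sig.resize(nn); p.rc.resize(nn); p.lam.resize(nn);
  p.rc_max = 0.0;
  for (int i = 0; i < p.ntypes; ++i)
    for (int j = 0; j < p.ntypes; ++j) {
      int k = i * p.ntypes + j;
      p.eps[k] = eps(i, j); p.sig[k] = sig(i, j); p.rc[k] = rc(i, j);
      double l = lam(i, j);
      p.lam[k] = R_IsNA(l) ? -1.0 : l;
      if (p.eps[k] > 0.0 && p.rc[k] > p.rc_max) p.rc_max = p.rc[k];
    }
  p.style = as<int>(pair["style"]);
  p.shift_force = as<bool>(pair["shift_force"]);
  return p;
}

TopoParams unpack_topo(List topo) {
  TopoParams t;
  IntegerMatrix bonds = topo["bonds"];
  t.nb = bonds.nrow();
  IntegerVector btype = topo["bond_type"];
  NumericVector bk = topo["bond_k"], br0 = topo["bond_r0"];
  t.b1.resize(t.nb); t.b2.resize(t.nb); t.btype.resize(t.nb);
  t.bk.resize(t.nb); t.br0.resize(t.nb);
  for (int b = 0; b < t.nb; ++b) {
    t.b1[b] = bonds(b, 0) - 1; t.b2[b] = bonds(b, 1) - 1;
    t.btype[b] = btype[b]; t.bk[b] = bk[b]; t.br0[b] = br0[b];
  }
  IntegerMatrix ang = topo["angles"];
  t.na = ang.nrow();
  NumericVector angk = topo["angle_k"], angt0 = topo["angle_theta0"];
  t.ai.resize(t.na); t.aj.resize(t.na); t.ak.resize(t.na);
  t.angk.resize(t.na); t.angt0.resize(t.na);
  for (int a = 0; a < t.na; ++a) {
    t.ai[a] = ang(a, 0) - 1; t.aj[a] = ang(a, 1) - 1; t.ak[a] = ang(a, 2) - 1;
    t.angk[a] = angk[a]; t.angt0[a] = angt0[a];
  }
  return t;
}

} // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector type, List box, List pair,
                List topo) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); ty[i] = type[i] - 1;
  }
  Box b = unpack_box(box);
  PairParams pp = unpack_pairs(pair);
  TopoParams tp = unpack_topo(topo);
  NeighborList nl; nl.skin = 0.0;
  nl.build(x, y, z, b, pp.rc_max);
  ForceOut out;
  compute_forces(x, y, z, ty, b, pp, tp, nl, out);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = out.fx[i]; F(i, 1) = out.fy[i]; F(i, 2) = out.fz[i];
  }
  NumericVector w(6);
  for (int k = 0; k < 6; ++k) w[k] = out.w[k];
  w.attr("names") = CharacterVector::create("xx", "yy", "zz", "xy", "xz", "yz");
  return List::create(_["forces"] = F, _["energy"] = out.energy,
                      _["virial"] = w);
}

// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix pos, List box) {
  int n = pos.nrow();
  Box b = unpack_box(box);
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      min_image(b, dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// BAOAB Langevin integrator with optional oscillatory xy shear
// (deforming tilted box + Lees-Edwards images, thermostat on peculiar
// velocities) and optional reflective x walls. Noise comes from R's RNG so
// set.seed() on the R side fixes the trajectory.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerMatrix image,
             IntegerVector type, List box, List pair, List topo,
             int nsteps, double dt, double temp, double gamma_damp,
             double gamma0, double omega, double t_start,
             int stress_stride, int traj_stride, double skin) {
  RNGScope rng;
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<int> ix(n), iy(n), iz(n), ty(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    ix[i] = image(i, 0); iy[i] = image(i, 1); iz[i] = image(i, 2);
    ty[i] = type[i] - 1;
  }
  Box b = unpack_box(box);
  PairParams pp = unpack_pairs(pair);
  TopoParams tp = unpack_topo(topo);
  double V = b.L[0] * b.L[1] * b.L[2];
  if (b.xwall) V = (b.xhi - b.xlo) * b.L[1] * b.L[2];

  bool shear = (gamma0 != 0.0 && omega > 0.0);
  double c1 = std::exp(-gamma_damp * dt);
  double c2 = std::sqrt(temp * (1.0 - c1 * c1));

  NeighborList nl; nl.skin = skin;
  ForceOut out;

  int nrec = (stress_stride > 0) ? nsteps / stress_stride : 0;
  NumericMatrix stress(nrec, 10); // t strain sxy sxz syz sxx syy szz Tkin pe
  int ntraj = (traj_stride > 0) ? nsteps / traj_stride : 0;
  List traj(ntraj);
  int irec = 0, itraj = 0;

  auto wrap = [&](int i) {
    if (b.per[2]) {
      int nz2 = (int)std::floor(z[i] / b.L[2]);
      if (nz2 != 0) { z[i] -= nz2 * b.L[2]; iz[i] += nz2; }
    }
    if (b.per[1]) {
      int ny2 = (int)std::floor(y[i] / b.L[1]);
      if (ny2 != 0) { y[i] -= ny2 * b.L[1]; x[i] -= ny2 * b.tilt; iy[i] += ny2; }
    }
    if (b.per[0]) {
      int nx2 = (int)std::floor(x[i] / b.L[0]);
      if (nx2 != 0) { x[i] -= nx2 * b.L[0]; ix[i] += nx2; }
    }
    if (b.xwall) {
      if (x[i] < b.xlo) { x[i] = 2.0 * b.xlo - x[i]; vx[i] = -vx[i]; }
      if (x[i] > b.xhi) { x[i] = 2.0 * b.xhi - x[i]; vx[i] = -vx[i]; }
      // a reflection that overshoots the opposite wall means the step was
      // unphysically large; clamp and let the blow-up guard report it
      if (x[i] < b.xlo) x[i] = b.xlo;
      if (x[i] > b.xhi) x[i] = b.xhi;
    }
  };

  if (nl.stale(x, y, z, b)) nl.build(x, y, z, b, pp.rc_max);
  compute_forces(x, y, z, ty, b, pp, tp, nl, out);

  auto check_finite = [&](int step) {
    if (!std::isfinite(out.energy)) {
      std::ostringstream msg;
      msg << "simulation blow-up: non-finite energy/forces at step " << step;
      stop(msg.str());
    }
  };
  check_finite(0);

  double t = t_start;
  for (int step = 0; step < nsteps; ++step) {
    double gam_now = shear ? gamma0 * std::sin(omega * t) : 0.0;
    double gam_next = shear ? gamma0 * std::sin(omega * (t + dt)) : 0.0;
    double gdot = shear ? gamma0 * omega * std::cos(omega * (t + 0.5 * dt)) : 0.0;

    // B
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * out.fx[i];
      vy[i] += 0.5 * dt * out.fy[i];
      vz[i] += 0.5 * dt * out.fz[i];
    }
    // A (half)
    for (int i = 0; i < n; ++i) {
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    // O on peculiar velocities
    if (gamma_damp > 0.0) {
      for (int i = 0; i < n; ++i) {
        double ux = vx[i] - gdot * y[i];
        vx[i] = gdot * y[i] + c1 * ux + c2 * norm_rand();
        vy[i] = c1 * vy[i] + c2 * norm_rand();
        vz[i] = c1 * vz[i] + c2 * norm_rand();
      }
    }
    // A (half) + affine deformation of this step
    double dgam = gam_next - gam_now;
    for (int i = 0; i < n; ++i) {
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
      if (shear) x[i] += dgam * y[i];
      wrap(i);
    }
    if (shear) b.tilt = gam_next * b.L[1];

    if (nl.stale(x, y, z, b)) nl.build(x, y, z, b, pp.rc_max);
    compute_forces(x, y, z, ty, b, pp, tp, nl, out);
    check_finite(step + 1);
    // B
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * out.fx[i];
      vy[i] += 0.5 * dt * out.fy[i];
      vz[i] += 0.5 * dt * out.fz[i];
    }
    t = t_start + (step + 1) * dt;

    if (stress_stride > 0 && (step + 1) % stress_stride == 0 && irec < nrec) {
      double gd_now = shear ? gamma0 * omega * std::cos(omega * t) : 0.0;
      double kxx = 0, kyy = 0, kzz = 0, kxy = 0, kxz = 0, kyz = 0, ke = 0;
      for (int i = 0; i < n; ++i) {
        double ux = vx[i] - gd_now * y[i]; // peculiar
        kxx += ux * ux; kyy += vy[i] * vy[i]; kzz += vz[i] * vz[i];
        kxy += ux * vy[i]; kxz += ux * vz[i]; kyz += vy[i] * vz[i];
        ke += ux * ux + vy[i] * vy[i] + vz[i] * vz[i];
      }
      stress(irec, 0) = t;
      stress(irec, 1) = shear ? gamma0 * std::sin(omega * t) : 0.0;
      // off-diagonals: material shear stress (negative of the pressure-
      // tensor component), so an elastic solid strained by +gamma reports
      // +G gamma; diagonals stay pressure-positive (ideal gas -> +rho kB T)
      stress(irec, 2) = -(kxy + out.w[3]) / V;
      stress(irec, 3) = -(kxz + out.w[4]) / V;
      stress(irec, 4) = -(kyz + out.w[5]) / V;
      stress(irec, 5) = (kxx + out.w[0]) / V;
      stress(irec, 6) = (kyy + out.w[1]) / V;
      stress(irec, 7) = (kzz + out.w[2]) / V;
      stress(irec, 8) = ke / (3.0 * n);
      stress(irec, 9) = out.energy;
      irec++;
    }
    if (traj_stride > 0 && (step + 1) % traj_stride == 0 && itraj < ntraj) {
      NumericMatrix fr(n, 3); // unwrapped coordinates
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = x[i] + ix[i] * b.L[0] + iy[i] * b.tilt;
        fr(i, 1) = y[i] + iy[i] * b.L[1];
        fr(i, 2) = z[i] + iz[i] * b.L[2];
      }
      traj[itraj++] = fr;
    }
    if ((step & 1023) == 0) checkUserInterrupt();
  }

  NumericMatrix P(n, 3), Vl(n, 3);
  IntegerMatrix I(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i];
    Vl(i, 0) = vx[i]; Vl(i, 1) = vy[i]; Vl(i, 2) = vz[i];
    I(i, 0) = ix[i]; I(i, 1) = iy[i]; I(i, 2) = iz[i];
  }
  colnames(stress) = CharacterVector::create(
      "t", "strain", "sxy", "sxz", "syz", "sxx", "syy", "szz", "Tkin", "pe");
  return List::create(_["pos"] = P, _["vel"] = Vl, _["image"] = I,
                      _["tilt"] = b.tilt, _["t_end"] = t,
                      _["stress"] = stress, _["traj"] = traj,
                      _["energy"] = out.energy);
}
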