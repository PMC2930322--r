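#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG: splitmix64-seeded xoshiro256+ with Marsaglia polar
// normals. Independent of R's RNG so trajectories are bit-reproducible from
// the integer seed recorded in the run config.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Periodic substrate force table.
// Triangular ("hexagonal") lattice of adhesion beads in the z = 0 plane,
// spacing a, treated as infinite and periodic over the rectangular cell
// a x (sqrt(3) a) holding two basis beads: (x0, y0) and (x0 + a/2,
// y0 + sqrt(3)/2 a). Forces on a probe bead are the exact Lennard-Jones
// lattice sums (eps, sigma = distance of zero force, cutoff rc) evaluated on
// a grid over (cell x, cell y, z) and trilinearly interpolated at run time.
// ---------------------------------------------------------------------------
struct SubTable {
  double a = 0, cellY = 0, x0 = 0, y0 = 0;
  double zmin = 0.05, zmax = 0, dx = 0, dy = 0, dz = 0;
  int nx = 0, ny = 0, nz = 0;
  double eps = 0, sigma = 0, rc = 0;
  std::vector<double> fx, fy, fz, en;
  bool active = false;

  inline int idx(int i, int j, int k) const { return (k * ny + j) * nx + i; }

  void build(double a_, double x0_, double y0_, double eps_, double sigma_,
             double rc_, double dgrid, double dzgrid) {
    a = a_; x0 = x0_; y0 = y0_; eps = eps_; sigma = sigma_; rc = rc_;
    cellY = std::sqrt(3.0) * a;
    nx = std::max(8, (int)std::ceil(a / dgrid)) + 1;
    ny = std::max(8, (int)std::ceil(cellY / dgrid)) + 1;
    zmax = rc + 0.3;
    nz = std::max(8, (int)std::ceil((zmax - zmin) / dzgrid)) + 1;
    dx = a / (nx - 1); dy = cellY / (ny - 1); dz = (zmax - zmin) / (nz - 1);
    size_t n = (size_t)nx * ny * nz;
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0); en.assign(n, 0.0);
    // lattice images within rc of any point of the cell
    int mi = (int)std::ceil((rc + a) / a) + 1;
    int mj = (int)std::ceil((rc + cellY) / cellY) + 1;
    double s6 = std::pow(sigma, 6.0), rc2 = rc * rc;
    for (int k = 0; k < nz; k++) {
      double z = zmin + k * dz;
      for (int j = 0; j < ny; j++) {
        double py = j * dy;
        for (int i = 0; i < nx; i++) {
          double px = i * dx;
          double Fx = 0, Fy = 0, Fz = 0, U = 0;
          for (int jj = -mj; jj <= mj; jj++) {
            for (int ii = -mi; ii <= mi; ii++) {
              for (int b = 0; b < 2; b++) {
                double bx = ii * a + (b ? 0.5 * a : 0.0);
                double by = jj * cellY + (b ? 0.5 * cellY : 0.0);
                double ddx = px - bx, ddy = py - by;
                double r2 = ddx * ddx + ddy * ddy + z * z;
                if (r2 > rc2 || r2 <= 0) continue;
                double inv2 = 1.0 / r2;
                double sr6 = s6 * inv2 * inv2 * inv2;
                U += eps * (sr6 * sr6 - 2.0 * sr6);
                // dU/dr * (1/r) = eps * (-12 sr12 + 12 sr6) / r^2
                double g = 12.0 * eps * (sr6 - sr6 * sr6) * inv2; // = (dU/dr)/r
                Fx -= g * ddx; Fy -= g * ddy; Fz -= g * z;
              }
            }
          }
          size_t id = idx(i, j, k);
          fx[id] = Fx; fy[id] = Fy; fz[id] = Fz; en[id] = U;
        }
      }
    }
    active = true;
  }

  // trilinear interpolation of force (and optionally energy) at (x, y, z)
  inline void force(double x, double y, double z, double &Fx, double &Fy,
                    double &Fz) const {
    if (z >= zmax) { Fx = Fy = Fz = 0; return; }
    double ux = (x - x0) / a, uy = (y - y0) / cellY;
    double px = (ux - std::floor(ux)) * a;
    double py = (uy - std::floor(uy)) * cellY;
    double zz = z < zmin ? zmin : z;
    double gi = px / dx, gj = py / dy, gk = (zz - zmin) / dz;
    int i0 = (int)gi, j0 = (int)gj, k0 = (int)gk;
    if (i0 >= nx - 1) i0 = nx - 2;
    if (j0 >= ny - 1) j0 = ny - 2;
    if (k0 >= nz - 1) k0 = nz - 2;
    double tx = gi - i0, ty = gj - j0, tz = gk - k0;
    double w[8] = {
      (1 - tx) * (1 - ty) * (1 - tz), tx * (1 - ty) * (1 - tz),
      (1 - tx) * ty * (1 - tz),       tx * ty * (1 - tz),
      (1 - tx) * (1 - ty) * tz,       tx * (1 - ty) * tz,
      (1 - tx) * ty * tz,             tx * ty * tz };
    int id[8] = { idx(i0, j0, k0),     idx(i0 + 1, j0, k0),
                  idx(i0, j0 + 1, k0), idx(i0 + 1, j0 + 1, k0),
                  idx(i0, j0, k0 + 1),     idx(i0 + 1, j0, k0 + 1),
                  idx(i0, j0 + 1, k0 + 1), idx(i0 + 1, j0 + 1, k0 + 1) };
    Fx = Fy = Fz = 0;
    for (int q = 0; q < 8; q++) {
      Fx += w[q] * fx[id[q]]; Fy += w[q] * fy[id[q]]; Fz += w[q] * fz[id[q]];
    }
    if (z < zmin) {
      // below the tabulated range the wall is steeply repulsive; extend the
      // bottom-slice vertical force linearly to keep the step finite
      Fz += (zmin - z) * 1e4;
    }
  }
};

// force field / run parameters passed from R ------------------------------
struct Params {
  double dt, gamma, kBT;
  double bond_k, crosslink_k;
  double ev_eps, ev_sigma;
  double coulomb, debye, cutoff; // coulomb = 332.06/eps_r in kcal*A... (nm units, prefactor given directly)
  double ca_eps, ca_range;
  double pull_f, pull_z;
  bool substrate;
  double ext_lo_x, ext_hi_x, ext_lo_y, ext_hi_y; // allowed xy box (extent - margin)
};

// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix pos0, IntegerMatrix bonds, NumericVector bond_b0,
                IntegerMatrix angles, NumericVector angle_k,
                IntegerMatrix crosslinks, NumericVector crosslink_b0,
                NumericVector charge, List par, List substrate,
                double n_steps_d, int record_every, double seed_d,
                bool zero_temperature) {
  const int N = pos0.nrow();
  const long long n_steps = (long long)n_steps_d;
  Params P;
  P.dt = as<double>(par["dt"]); P.gamma = as<double>(par["friction"]);
  P.kBT = as<double>(par["kBT"]);
  P.bond_k = as<double>(par["bond_k"]);
  P.crosslink_k = as<double>(par["crosslink_k"]);
  P.ev_eps = as<double>(par["excluded_eps"]);
  P.ev_sigma = as<double>(par["excluded_sigma"]);
  P.coulomb = as<double>(par["coulomb_prefactor"]);
  P.debye = as<double>(par["debye_length"]);
  P.cutoff = as<double>(par["cutoff"]);
  P.ca_eps = as<double>(par["ca_eps"]);
  P.ca_range = as<double>(par["ca_range"]);
  P.pull_f = as<double>(par["pull_force_per_bead"]);
  P.pull_z = as<double>(par["pull_z_threshold"]);
  P.substrate = substrate.size() > 0;

  SubTable tab;
  if (P.substrate) {
    tab.build(as<double>(substrate["spacing"]), as<double>(substrate["x0"]),
              as<double>(substrate["y0"]), as<double>(substrate["eps"]),
              as<double>(substrate["sigma"]), as<double>(substrate["cutoff"]),
              0.02, 0.02);
    P.ext_lo_x = as<double>(substrate["xlo"]); P.ext_hi_x = as<double>(substrate["xhi"]);
    P.ext_lo_y = as<double>(substrate["ylo"]); P.ext_hi_y = as<double>(substrate["yhi"]);
  }

  std::vector<double> x(N), y(N), z(N);
  for (int i = 0; i < N; i++) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2); }

  // exclusions: bonded (1-2) and crosslinked pairs skip nonbonded terms
  std::vector<std::vector<int>> excl(N);
  auto add_excl = [&](int i, int j) {
    excl[i].push_back(j); excl[j].push_back(i);
  };
  for (int b = 0; b < bonds.nrow(); b++) add_excl(bonds(b, 0), bonds(b, 1));
  for (int c = 0; c < crosslinks.nrow(); c++) add_excl(crosslinks(c, 0), crosslinks(c, 1));
  auto excluded = [&](int i, int j) {
    for (int k : excl[i]) if (k == j) return true;
    return false;
  };

  // Verlet neighbour list
  const double skin = 0.4;
  const double rlist = P.cutoff + skin;
  std::vector<int> nl_i, nl_j;
  std::vector<double> x0v(N), y0v(N), z0v(N);
  auto build_list = [&]() {
    nl_i.clear(); nl_j.clear();
    double rl2 = rlist * rlist;
    for (int i = 0; i < N; i++) {
      for (int j = i + 1; j < N; j++) {
        double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
        if (ddx * ddx + ddy * ddy + ddz * ddz < rl2 && !excluded(i, j)) {
          nl_i.push_back(i); nl_j.push_back(j);
        }
      }
    }
    for (int i = 0; i < N; i++) { x0v[i] = x[i]; y0v[i] = y[i]; z0v[i] = z[i]; }
  };
  auto max_disp2 = [&]() {
    double m = 0;
    for (int i = 0; i < N; i++) {
      double ddx = x[i] - x0v[i], ddy = y[i] - y0v[i], ddz = z[i] - z0v[i];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > m) m = d2;
    }
    return m;
  };
  build_list();

  Rng rng((uint64_t)seed_d);
  const double mob = P.dt / P.gamma;
  const double noise = zero_temperature ? 0.0 : std::sqrt(2.0 * P.kBT * P.dt / P.gamma);
  const double cut2 = P.cutoff * P.cutoff;
  const double ev6 = std::pow(P.ev_sigma, 6.0);

  long long n_frames = n_steps / record_every + 1;
  NumericVector frames((R_xlen_t)n_frames * N * 3);
  NumericVector times(n_frames);
  auto record = [&](long long f, double t) {
    R_xlen_t base = (R_xlen_t)f * N * 3;
    for (int i = 0; i < N; i++) {
      frames[base + i] = x[i];
      frames[base + N + i] = y[i];
      frames[base + 2 * N + i] = z[i];
    }
    times[f] = t;
  };
  record(0, 0.0);

  std::vector<double> Fx(N), Fy(N), Fz(N);
  bool out_of_extent = false;
  long long bad_step = -1;

  for (long long step = 1; step <= n_steps; step++) {
    std::fill(Fx.begin(), Fx.end(), 0.0);
    std::fill(Fy.begin(), Fy.end(), 0.0);
    std::fill(Fz.begin(), Fz.end(), 0.0);

    // bonds
    for (int b = 0; b < bonds.nrow(); b++) {
      int i = bonds(b, 0), j = bonds(b, 1);
      double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      double g = P.bond_k * (r - bond_b0[b]) / r;
      Fx[i] += g * ddx; Fy[i] += g * ddy; Fz[i] += g * ddz;
      Fx[j] -= g * ddx; Fy[j] -= g * ddy; Fz[j] -= g * ddz;
    }
    // crosslinks (harmonic)
    for (int c = 0; c < crosslinks.nrow(); c++) {
      int i = crosslinks(c, 0), j = crosslinks(c, 1);
      double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      double g = P.crosslink_k * (r - crosslink_b0[c]) / r;
      Fx[i] += g * ddx; Fy[i] += g * ddy; Fz[i] += g * ddz;
      Fx[j] -= g * ddx; Fy[j] -= g * ddy; Fz[j] -= g * ddz;
    }
    // angles: U = 0.5 k (theta - pi)^2 about the straight state == 0.5 k th^2
    // with th the deviation angle; standard three-body forces
    for (int a = 0; a < angles.nrow(); a++) {
      int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
      double ax = x[i] - x[j], ay = y[i] - y[j], az = z[i] - z[j];
      double bx2 = x[k] - x[j], by2 = y[k] - y[j], bz2 = z[k] - z[j];
      double ra = std::sqrt(ax * ax + ay * ay + az * az);
      double rb = std::sqrt(bx2 * bx2 + by2 * by2 + bz2 * bz2);
      double cs = (ax * bx2 + ay * by2 + az * bz2) / (ra * rb);
      if (cs > 1.0) cs = 1.0;
      if (cs < -1.0) cs = -1.0;
      double th = std::acos(cs);           // bond angle, pi when straight
      double dev = M_PI - th;              // deviation from straight
      double sn = std::sqrt(1.0 - cs * cs);
      if (sn < 1e-8) sn = 1e-8;
      // dU/dtheta = -k * dev ; F = -(dU/dtheta) dtheta/dr
      double coef = -angle_k[a] * dev / sn;
      double fi_x = coef * (bx2 / (ra * rb) - cs * ax / (ra * ra));
      double fi_y = coef * (by2 / (ra * rb) - cs * ay / (ra * ra));
      double fi_z = coef * (bz2 / (ra * rb) - cs * az / (ra * ra));
      double fk_x = coef * (ax / (ra * rb) - cs * bx2 / (rb * rb));
      double fk_y = coef * (ay / (ra * rb) - cs * by2 / (rb * rb));
      double fk_z = coef * (az / (ra * rb) - cs * bz2 / (rb * rb));
      Fx[i] += fi_x; Fy[i] += fi_y; Fz[i] += fi_z;
      Fx[k] += fk_x; Fy[k] += fk_y; Fz[k] += fk_z;
      Fx[j] -= fi_x + fk_x; Fy[j] -= fi_y + fk_y; Fz[j] -= fi_z + fk_z;
    }
    // nonbonded: WCA excluded volume + screened Coulomb + optional Ca well
    for (size_t p = 0; p < nl_i.size(); p++) {
      int i = nl_i[p], j = nl_j[p];
      double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      double g = 0.0; // (dU/dr)/r ; F_i -= g * dr_ij
      if (r < P.ev_sigma && P.ev_eps > 0) {
        double inv2 = 1.0 / r2;
        double sr6 = ev6 * inv2 * inv2 * inv2;
        g += 12.0 * P.ev_eps * (sr6 - sr6 * sr6) * inv2;
      }
      double qq = charge[i] * charge[j];
      if (qq != 0.0 && P.coulomb != 0.0) {
        double u = P.coulomb * qq * std::exp(-r / P.debye) / r;
        g += -u * (1.0 / r + 1.0 / P.debye) / r;
      }
      if (P.ca_eps > 0.0) {
        double e = std::exp(-r2 / (P.ca_range * P.ca_range));
        g += P.ca_eps * 2.0 * e / (P.ca_range * P.ca_range); // dU/dr /r of -eps exp(-(r/rc)^2)
      }
      Fx[i] -= g * ddx; Fy[i] -= g * ddy; Fz[i] -= g * ddz;
      Fx[j] += g * ddx; Fy[j] += g * ddy; Fz[j] += g * ddz;
    }
    // substrate + deposition pull
    if (P.substrate) {
      for (int i = 0; i < N; i++) {
        double sfx, sfy, sfz;
        tab.force(x[i], y[i], z[i], sfx, sfy, sfz);
        Fx[i] += sfx; Fy[i] += sfy; Fz[i] += sfz;
        if (z[i] > P.pull_z) Fz[i] -= P.pull_f;
      }
    }

    // overdamped update
    double max_move = 0.0;
    for (int i = 0; i < N; i++) {
      double mx = mob * Fx[i] + noise * (noise > 0 ? rng.norm() : 0.0);
      double my = mob * Fy[i] + noise * (noise > 0 ? rng.norm() : 0.0);
      double mz = mob * Fz[i] + noise * (noise > 0 ? rng.norm() : 0.0);
      double m2 = mx * mx + my * my + mz * mz;
      if (m2 > max_move) max_move = m2;
      x[i] += mx; y[i] += my; z[i] += mz;
    }
    if (!std::isfinite(max_move) || max_move > 1.0) { bad_step = step; break; }
    if (P.substrate) {
      for (int i = 0; i < N; i++) {
        if (x[i] < P.ext_lo_x || x[i] > P.ext_hi_x ||
            y[i] < P.ext_lo_y || y[i] > P.ext_hi_y) { out_of_extent = true; break; }
      }
      if (out_of_extent) { bad_step = step; break; }
    }
    if (max_disp2() > 0.25 * skin * skin) build_list();
    if (step % record_every == 0) record(step / record_every, step * P.dt);
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  frames.attr("dim") = IntegerVector::create((int)N, 3, (int)n_frames);
  // note: stored frame-major above (base + col*N + i), i.e. dim (N, 3, frame)
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["n_beads"] = N, _["n_frames"] = (double)n_frames,
                      _["failed_step"] = (double)bad_step,
                      _["out_of_extent"] = out_of_extent);
}

// ---------------------------------------------------------------------------
// 8-connected labelling of a logical mask (two-pass union-find).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j)) continue;
      int best = 0;
      int di[4] = { -1, -1, 0, 1 }, dj[4] = { 0, -1, -1, -1 };
      int neigh[4];
      int nn = 0;
      for (int q = 0; q < 4; q++) {
        int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || jj < 0 || ii >= nr) continue;
        int l = lab(ii, jj);
        if (l > 0) { neigh[nn++] = l; if (best == 0 || l < best) best = l; }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
        for (int q = 0; q < nn; q++) unite(best, neigh[q]);
      }
    }
  }
  // second pass: flatten and renumber densely
  std::vector<int> newlab(next, 0);
  int count = 0;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find(l);
      if (newlab[r] == 0) newlab[r] = ++count;
      lab(i, j) = newlab[r];
    }
  }
  lab.attr("n_objects") = count;
  return lab;
}
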