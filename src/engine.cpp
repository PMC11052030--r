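// DPD engine: pair forces, bonded potentials (WLC+POW, harmonic bond/angle,
// cosine dihedral), membrane area/volume constraints, Bell-model binding
// kinetics, modified velocity-Verlet integration with prescribed rigid-body
// drivers, and trajectory/observable recording.
//
// All quantities are in reduced DPD units (kBT is the energy scale).
// Positions live in a box with origin 0; per-dimension periodic flags select
// minimum-image wrapping.  Frozen particles exert forces but are never
// integrated; driven particles are frozen particles whose positions follow a
// prescribed motion.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// Fast counter-based PRNG (splitmix64) with cached polar-method normals:
// the engine draws one or more normal deviates per interacting pair per
// step, so generator speed dominates the step cost.
struct FastRng {
  uint64_t state;
  double cache = 0.0;
  bool has_cache = false;
  explicit FastRng(uint64_t seed) : state(seed) {}
  inline uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() {  // in (0, 1)
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0) +
           5.551115123125783e-17;
  }
  inline double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f;
    has_cache = true;
    return u * f;
  }
};

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

struct DynBond { int i, j, kind; double r0; };

struct Driver {
  int mode;                  // 0 translate, 1 oscillate
  std::vector<int> idx;      // 0-based particle indices
  Vec3 vel;                  // translate
  Vec3 axis;                 // oscillate
  double amp, freq;
  std::vector<Vec3> base;    // unwrapped base positions at run start
};

struct Energies {
  double pair_cons = 0, elastic = 0, harm = 0, dynb = 0, angle = 0,
         dihedral = 0, area_global = 0, area_local = 0, volume = 0,
         external = 0;
  double total() const {
    return pair_cons + elastic + harm + dynb + angle + dihedral +
           area_global + area_local + volume + external;
  }
};

struct World {
  int N = 0, S = 0;
  std::vector<Vec3> pos, vel;
  std::vector<int> type, img_x, img_y, img_z;
  std::vector<char> frozen;
  double box[3] = {0, 0, 0};
  bool periodic[3] = {false, false, false};
  std::vector<double> pair_a, pair_g, pair_rc;  // S x S row-major
  double kBT = 1.0, dt = 0.005, lambda = 0.5;
  double rc_max = 0.0;

  // WLC + POW membrane bonds
  std::vector<int> wlc_i, wlc_j;
  std::vector<double> wlc_l0, wlc_lmax, wlc_kp;
  double wlc_p = 1.0, wlc_m = 2.0, wlc_gamma = 0.0, wlc_gamma_t = 0.0;

  // static harmonic bonds (filament backbones)
  std::vector<int> hb_i, hb_j;
  std::vector<double> hb_r0, hb_k;

  // dynamic bonds (ACP-filament kind 0, membrane-filament kind 1)
  std::vector<DynBond> dyn;
  double dyn_k[2] = {0, 0};

  // angles, dihedrals
  std::vector<int> an_i, an_j, an_k;
  std::vector<double> an_t0, an_kk;
  std::vector<int> di_i, di_j, di_k, di_l;
  std::vector<double> di_t0, di_kk;

  // membrane surface constraints
  bool has_mem = false;
  std::vector<int> fc_a, fc_b, fc_c;
  std::vector<double> face_a0;
  double A0 = 0, V0 = 0, ka = 0, kv = 0, kd = 0;

  // binding kinetics
  bool has_bind = false;
  double kon0 = 0, koff0 = 0, sig_on[2] = {0, 0}, sig_off[2] = {0, 0};
  double don = 0, doff = 0, cand_l0 = 0;
  int bind_every = 10;
  std::vector<int> nlink0, nlink1;  // per-particle dyn-link counts by kind

  // aspiration field
  bool has_asp = false;
  Vec3 asp_p, asp_u;
  double asp_f = 0, asp_rad = 0, asp_smin = 0, asp_smax = 0;

  // weak per-particle Langevin background (numerical stabiliser)
  double bg_gamma = 0.0;

  // rupture halt rule on WLC bonds
  bool has_rupture = false;
  double rupture_factor = 2.0;

  std::vector<Driver> drivers;
  std::vector<int> group;  // 0 = none
  int ngroups = 0;
};

inline double wrap1(double x, double L) {
  // into [0, L)
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

inline Vec3 minimg(const World& w, Vec3 d) {
  if (w.periodic[0]) d.x -= w.box[0] * std::round(d.x / w.box[0]);
  if (w.periodic[1]) d.y -= w.box[1] * std::round(d.y / w.box[1]);
  if (w.periodic[2]) d.z -= w.box[2] * std::round(d.z / w.box[2]);
  return d;
}

// ---------------------------------------------------------------- neighbors

void brute_pairs(const World& w, double rmax,
                 std::vector<std::pair<int, int>>& out) {
  const double r2 = rmax * rmax;
  for (int i = 0; i < w.N; ++i)
    for (int j = i + 1; j < w.N; ++j) {
      Vec3 d = minimg(w, w.pos[i] - w.pos[j]);
      if (d.norm2() < r2) out.emplace_back(i, j);
    }
}

void cell_pairs(const World& w, double rmax,
                std::vector<std::pair<int, int>>& out) {
  // grid bounds: box for periodic dims, data bounds otherwise
  double lo[3], len[3];
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    if (w.periodic[d]) {
      lo[d] = 0.0; len[d] = w.box[d];
    } else {
      double mn = 1e300, mx = -1e300;
      for (int i = 0; i < w.N; ++i) {
        double v = (d == 0 ? w.pos[i].x : (d == 1 ? w.pos[i].y : w.pos[i].z));
        mn = std::min(mn, v); mx = std::max(mx, v);
      }
      lo[d] = mn - 1e-9; len[d] = (mx - mn) + 2e-9;
    }
    nc[d] = std::max(1, (int)std::floor(len[d] / rmax));
    if (w.periodic[d] && nc[d] < 3) { brute_pairs(w, rmax, out); return; }
  }
  const int ncells = nc[0] * nc[1] * nc[2];
  if (ncells <= 1 || w.N < 64) { brute_pairs(w, rmax, out); return; }

  std::vector<int> head(ncells, -1), nxt(w.N, -1), cellof(w.N);
  auto cidx = [&](const Vec3& p) {
    int c[3];
    const double v[3] = {p.x, p.y, p.z};
    for (int d = 0; d < 3; ++d) {
      int k = (int)std::floor((v[d] - lo[d]) / len[d] * nc[d]);
      if (k < 0) k = 0;
      if (k >= nc[d]) k = nc[d] - 1;
      c[d] = k;
    }
    return (c[2] * nc[1] + c[1]) * nc[0] + c[0];
  };
  for (int i = 0; i < w.N; ++i) {
    int c = cidx(w.pos[i]);
    cellof[i] = c; nxt[i] = head[c]; head[c] = i;
  }
  const double r2 = rmax * rmax;
  std::vector<int> nbr;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int c = (cz * nc[1] + cy) * nc[0] + cx;
        if (head[c] < 0) continue;
        nbr.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int gx = cx + dx, gy = cy + dy, gz = cz + dz;
              if (w.periodic[0]) gx = (gx + nc[0]) % nc[0];
              else if (gx < 0 || gx >= nc[0]) continue;
              if (w.periodic[1]) gy = (gy + nc[1]) % nc[1];
              else if (gy < 0 || gy >= nc[1]) continue;
              if (w.periodic[2]) gz = (gz + nc[2]) % nc[2];
              else if (gz < 0 || gz >= nc[2]) continue;
              int g = (gz * nc[1] + gy) * nc[0] + gx;
              if (g >= c && std::find(nbr.begin(), nbr.end(), g) == nbr.end())
                nbr.push_back(g);
            }
        for (int g : nbr) {
          for (int i = head[c]; i >= 0; i = nxt[i]) {
            int jstart = (g == c) ? nxt[i] : head[g];
            for (int j = jstart; j >= 0; j = nxt[j]) {
              Vec3 d = minimg(w, w.pos[i] - w.pos[j]);
              if (d.norm2() < r2) {
                if (i < j) out.emplace_back(i, j);
                else out.emplace_back(j, i);
              }
            }
          }
        }
      }
}

// ------------------------------------------------------------------- forces

// WLC attraction magnitude (positive number) at extension ratio x
inline double wlc_attract(double kBT, double p, double x) {
  double om = 1.0 - x;
  return (kBT / p) * (1.0 / (4.0 * om * om) - 0.25 + x);
}

void add_pair_forces(World& w, const std::vector<std::pair<int, int>>& nl,
                     const std::vector<Vec3>& vel, std::vector<Vec3>& F,
                     bool stochastic, FastRng* rng, Energies* E) {
  const double inv_sqrt_dt = 1.0 / std::sqrt(w.dt);
  for (const auto& pr : nl) {
    const int i = pr.first, j = pr.second;
    if (w.frozen[i] && w.frozen[j]) continue;
    const int ti = w.type[i], tj = w.type[j];
    // holding (5) vs injection (6) micropipette interaction is disregarded
    if ((ti == 5 && tj == 6) || (ti == 6 && tj == 5)) continue;
    const double rc = w.pair_rc[ti * w.S + tj];
    if (rc <= 0) continue;
    Vec3 d = minimg(w, w.pos[i] - w.pos[j]);
    const double r2 = d.norm2();
    if (r2 >= rc * rc) continue;
    const double r = std::sqrt(r2);
    if (r < 1e-12) stop("overlapping particles %d and %d", i + 1, j + 1);
    const Vec3 rh = d * (1.0 / r);
    const double a = w.pair_a[ti * w.S + tj];
    const double wfac = 1.0 - r / rc;  // omega^R; omega^D = wfac^2
    double fmag = a * wfac;
    if (E) E->pair_cons += 0.5 * a * rc * wfac * wfac;
    if (stochastic) {
      const double g = w.pair_g[ti * w.S + tj];
      if (g > 0) {
        const double sig = std::sqrt(2.0 * g * w.kBT);
        const Vec3 vij = vel[i] - vel[j];
        fmag += -g * wfac * wfac * vij.dot(rh);
        fmag += sig * wfac * rng->norm() * inv_sqrt_dt;
      }
    }
    const Vec3 f = rh * fmag;
    F[i] += f;
    F[j] -= f;
  }
}

void add_wlc_forces(World& w, const std::vector<Vec3>& vel,
                    std::vector<Vec3>& F, bool stochastic,
                    FastRng* rng, Energies* E) {
  const double inv_sqrt_dt = 1.0 / std::sqrt(w.dt);
  const double sig_b = std::sqrt(2.0 * w.wlc_gamma * w.kBT);
  const double sig_t = std::sqrt(2.0 * w.wlc_gamma_t * w.kBT);
  for (size_t b = 0; b < w.wlc_i.size(); ++b) {
    const int i = w.wlc_i[b], j = w.wlc_j[b];
    if (w.frozen[i] && w.frozen[j]) continue;  // internal to a rigid wall
    Vec3 d = minimg(w, w.pos[i] - w.pos[j]);
    double l = d.norm();
    const double lmax = w.wlc_lmax[b];
    if (l >= 0.999 * lmax) {
      if (w.has_rupture) l = 0.999 * lmax;  // halt rule fires this step
      else stop("membrane bond %d reached its contour length", (int)b + 1);
    }
    const double x = l / lmax;
    const Vec3 rh = d * (1.0 / l);
    // positive = repulsive (pushes i and j apart)
    double fmag = w.wlc_kp[b] / std::pow(l, w.wlc_m) -
                  wlc_attract(w.kBT, w.wlc_p, x);
    if (E) {
      const double om = 1.0 - x;
      E->elastic += w.kBT * lmax / (4.0 * w.wlc_p) *
                    (3.0 * x * x - 2.0 * x * x * x) / om;
      if (std::abs(w.wlc_m - 1.0) < 1e-12)
        E->elastic += -w.wlc_kp[b] * std::log(l);
      else
        E->elastic += w.wlc_kp[b] / ((w.wlc_m - 1.0) * std::pow(l, w.wlc_m - 1.0));
    }
    Vec3 f = rh * fmag;
    if (stochastic && (w.wlc_gamma > 0 || w.wlc_gamma_t > 0)) {
      // membrane viscosity: central and tangential dissipation channels on
      // the bond, each with its fluctuation-dissipation-matched noise
      const Vec3 vij = vel[i] - vel[j];
      const double vpar = vij.dot(rh);
      f += rh * (-w.wlc_gamma * vpar + sig_b * rng->norm() * inv_sqrt_dt);
      if (w.wlc_gamma_t > 0) {
        const Vec3 vperp = vij - rh * vpar;
        const Vec3 xi(rng->norm(), rng->norm(), rng->norm());
        const Vec3 xperp = xi - rh * xi.dot(rh);
        f += vperp * (-w.wlc_gamma_t) + xperp * (sig_t * inv_sqrt_dt);
      }
    }
    F[i] += f;
    F[j] -= f;
  }
}

void add_harm_forces(World& w, std::vector<Vec3>& F, Energies* E) {
  auto one = [&](int i, int j, double r0, double k, double* acc) {
    if (w.frozen[i] && w.frozen[j]) return;  // internal to a rigid wall
    Vec3 d = minimg(w, w.pos[i] - w.pos[j]);
    const double r = d.norm();
    if (r < 1e-12) stop("zero-length bond between %d and %d", i + 1, j + 1);
    // U = k (r - r0)^2 (no 1/2 factor)
    const double fmag = -2.0 * k * (r - r0);
    const Vec3 f = d * (fmag / r);
    F[i] += f;
    F[j] -= f;
    if (acc) *acc += k * (r - r0) * (r - r0);
  };
  for (size_t b = 0; b < w.hb_i.size(); ++b)
    one(w.hb_i[b], w.hb_j[b], w.hb_r0[b], w.hb_k[b], E ? &E->harm : nullptr);
  for (const auto& db : w.dyn)
    one(db.i, db.j, db.r0, w.dyn_k[db.kind], E ? &E->dynb : nullptr);
}

void add_angle_forces(World& w, std::vector<Vec3>& F, Energies* E) {
  for (size_t a = 0; a < w.an_i.size(); ++a) {
    const int i = w.an_i[a], j = w.an_j[a], k = w.an_k[a];
    if (w.frozen[i] && w.frozen[j] && w.frozen[k]) continue;
    const Vec3 u = minimg(w, w.pos[i] - w.pos[j]);
    const Vec3 v = minimg(w, w.pos[k] - w.pos[j]);
    const double nu = u.norm(), nv = v.norm();
    double ct = u.dot(v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    const double th = std::acos(ct);
    const double dU = 2.0 * w.an_kk[a] * (th - w.an_t0[a]);  // U = k (th-t0)^2
    if (E) E->angle += w.an_kk[a] * (th - w.an_t0[a]) * (th - w.an_t0[a]);
    const Vec3 n = u.cross(v);
    const double nn = n.norm();
    if (nn < 1e-10) continue;  // at/near collinear: restoring torque vanishes
    // dtheta/du = -(u x n)/(|u|^2 |n|); force = -dU * dtheta/dr
    const Vec3 f_i = u.cross(n) * (-dU / (nu * nu * nn));
    const Vec3 f_k = n.cross(v) * (-dU / (nv * nv * nn));
    F[i] += f_i;
    F[k] += f_k;
    F[j] -= f_i + f_k;
  }
}

void add_dihedral_forces(World& w, std::vector<Vec3>& F, Energies* E,
                         bool strict) {
  for (size_t q = 0; q < w.di_i.size(); ++q) {
    const int i1 = w.di_i[q], i2 = w.di_j[q], i3 = w.di_k[q], i4 = w.di_l[q];
    if (w.frozen[i1] && w.frozen[i2] && w.frozen[i3] && w.frozen[i4])
      continue;
    const Vec3 b1 = minimg(w, w.pos[i2] - w.pos[i1]);
    const Vec3 b2 = minimg(w, w.pos[i3] - w.pos[i2]);
    const Vec3 b3 = minimg(w, w.pos[i4] - w.pos[i3]);
    const Vec3 c1 = b1.cross(b2), c2 = b2.cross(b3);
    const double n1 = c1.norm2(), n2 = c2.norm2(), nb2 = b2.norm();
    if (n1 < 1e-18 || n2 < 1e-18) {
      if (strict) stop("collinear triple in dihedral %d", (int)q + 1);
      continue;
    }
    // near-collinear triples make the torque arm 1/|c|^2 explode; the
    // twist angle is ill-defined there, so skip rather than kick the system
    if (!strict && (n1 < 2.5e-3 * b1.norm2() * nb2 * nb2 ||
                    n2 < 2.5e-3 * b3.norm2() * nb2 * nb2))
      continue;
    // phi = atan2(y, x) with x = c1.c2, y = |b2| b1.c2; differentiate the
    // atan2 form exactly: dphi = (x dy - y dx)/(x^2 + y^2)
    const double x = c1.dot(c2);
    const double y = nb2 * b1.dot(c2);
    const double phi = std::atan2(y, x);
    const double dU = w.di_kk[q] * std::sin(phi - w.di_t0[q]);
    if (E) E->dihedral += w.di_kk[q] * (1.0 - std::cos(phi - w.di_t0[q]));
    const double den = x * x + y * y;
    // gradients of x and y with respect to the bond vectors b1, b2, b3
    const Vec3 dx_b1 = b2.cross(c2);
    const Vec3 dx_b2 = c2.cross(b1) + b3.cross(c1);
    const Vec3 dx_b3 = c1.cross(b2);
    const Vec3 dy_b1 = c2 * nb2;
    const Vec3 dy_b2 = b2 * (b1.dot(c2) / nb2) + b3.cross(b1) * nb2;
    const Vec3 dy_b3 = c1 * nb2;
    const Vec3 g_b1 = (dy_b1 * x - dx_b1 * y) * (1.0 / den);
    const Vec3 g_b2 = (dy_b2 * x - dx_b2 * y) * (1.0 / den);
    const Vec3 g_b3 = (dy_b3 * x - dx_b3 * y) * (1.0 / den);
    // chain rule: b1 = r2-r1, b2 = r3-r2, b3 = r4-r3; force = -dU * dphi/dr
    F[i1] += g_b1 * dU;
    F[i2] += (g_b2 - g_b1) * dU;
    F[i3] += (g_b3 - g_b2) * dU;
    F[i4] -= g_b3 * dU;
  }
}

void add_surface_forces(World& w, std::vector<Vec3>& F, Energies* E) {
  if (!w.has_mem) return;
  const size_t NF = w.fc_a.size();
  std::vector<double> area(NF);
  double A = 0, V = 0;
  for (size_t f = 0; f < NF; ++f) {
    const Vec3& a = w.pos[w.fc_a[f]];
    const Vec3& b = w.pos[w.fc_b[f]];
    const Vec3& c = w.pos[w.fc_c[f]];
    const Vec3 n = (b - a).cross(c - a);
    area[f] = 0.5 * n.norm();
    if (area[f] < 1e-12) stop("degenerate face %d", (int)f + 1);
    A += area[f];
    V += a.dot(b.cross(c)) / 6.0;
  }
  if (V <= 0) stop("membrane mesh has non-positive enclosed volume");
  const double cA = -w.ka * (A - w.A0) / w.A0;        // dF = cA * dA/dx
  const double cV = -w.kv * (V - w.V0) / w.V0;
  if (E) {
    E->area_global += w.ka * (A - w.A0) * (A - w.A0) / (2.0 * w.A0);
    E->volume += w.kv * (V - w.V0) * (V - w.V0) / (2.0 * w.V0);
  }
  for (size_t f = 0; f < NF; ++f) {
    const int ia = w.fc_a[f], ib = w.fc_b[f], ic = w.fc_c[f];
    const Vec3& a = w.pos[ia];
    const Vec3& b = w.pos[ib];
    const Vec3& c = w.pos[ic];
    const Vec3 n = (b - a).cross(c - a);
    const Vec3 nh = n * (1.0 / n.norm());
    const double cL = -w.kd * (area[f] - w.face_a0[f]) / w.face_a0[f];
    if (E)
      E->area_local += w.kd * (area[f] - w.face_a0[f]) *
                       (area[f] - w.face_a0[f]) / (2.0 * w.face_a0[f]);
    const double cArea = cA + cL;
    // grad of triangle area wrt each vertex: 0.5 * nh x (opposite edge)
    F[ia] += nh.cross(c - b) * (0.5 * cArea);
    F[ib] += nh.cross(a - c) * (0.5 * cArea);
    F[ic] += nh.cross(b - a) * (0.5 * cArea);
    // grad of signed volume
    F[ia] += b.cross(c) * (cV / 6.0);
    F[ib] += c.cross(a) * (cV / 6.0);
    F[ic] += a.cross(b) * (cV / 6.0);
  }
}

// weak per-particle Langevin bath: removes slow numerical heating of
// sparsely-coupled networks over multi-million-step runs.  gamma_bg is
// chosen far below every physical friction in the model.
// applied every bath_stride steps with impulse-equivalent coefficients
// (valid because gamma_bg * stride * dt stays far below 1)
constexpr int kBathStride = 10;
void add_background_bath(World& w, const std::vector<Vec3>& vel,
                         std::vector<Vec3>& F, FastRng* rng) {
  if (w.bg_gamma <= 0 || rng == nullptr) return;
  const double g = w.bg_gamma * kBathStride;
  const double sig = std::sqrt(2.0 * g * w.kBT / w.dt);
  for (int i = 0; i < w.N; ++i) {
    if (w.frozen[i]) continue;
    F[i] += vel[i] * (-g) +
            Vec3(rng->norm(), rng->norm(), rng->norm()) * sig;
  }
}

void add_aspiration(World& w, std::vector<Vec3>& F, Energies* E) {
  if (!w.has_asp) return;
  for (int i = 0; i < w.N; ++i) {
    if (w.type[i] != 0 || w.frozen[i]) continue;  // membrane particles only
    const Vec3 d = w.pos[i] - w.asp_p;
    const double s = d.dot(w.asp_u);
    if (s < w.asp_smin || s > w.asp_smax) continue;
    const Vec3 rad = d - w.asp_u * s;
    if (rad.norm() > w.asp_rad) continue;
    F[i] += w.asp_u * w.asp_f;
    if (E) E->external += -w.asp_f * s;  // linear potential along the axis
  }
}

void compute_forces(World& w, const std::vector<std::pair<int, int>>& nl,
                    const std::vector<Vec3>& vel, std::vector<Vec3>& F,
                    bool stochastic, FastRng* rng, Energies* E,
                    bool strict_dihedral = false, bool bath_now = false) {
  std::fill(F.begin(), F.end(), Vec3());
  add_pair_forces(w, nl, vel, F, stochastic, rng, E);
  add_wlc_forces(w, vel, F, stochastic, rng, E);
  add_harm_forces(w, F, E);
  add_angle_forces(w, F, E);
  add_dihedral_forces(w, F, E, strict_dihedral);
  add_surface_forces(w, F, E);
  add_aspiration(w, F, E);
  if (stochastic && bath_now) add_background_bath(w, vel, F, rng);
}

// ------------------------------------------------------------- world parsing

std::vector<int> as_idx0(SEXP s) {
  IntegerVector v(s);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

World parse_world(const List& world) {
  World w;
  NumericMatrix pos = world["pos"], vel = world["vel"];
  w.N = pos.nrow();
  w.pos.resize(w.N); w.vel.resize(w.N);
  for (int i = 0; i < w.N; ++i) {
    w.pos[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
    w.vel[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));
  }
  IntegerVector tp = world["type"];
  LogicalVector fr = world["frozen"];
  w.type.assign(tp.begin(), tp.end());
  w.frozen.resize(w.N);
  for (int i = 0; i < w.N; ++i) w.frozen[i] = fr[i] ? 1 : 0;
  w.img_x.assign(w.N, 0); w.img_y.assign(w.N, 0); w.img_z.assign(w.N, 0);
  NumericVector box = world["box"];
  LogicalVector per = world["periodic"];
  for (int d = 0; d < 3; ++d) { w.box[d] = box[d]; w.periodic[d] = per[d]; }
  NumericMatrix A = world["pair_a"], G = world["pair_gamma"], RC = world["pair_rc"];
  w.S = A.nrow();
  w.pair_a.resize(w.S * w.S); w.pair_g.resize(w.S * w.S); w.pair_rc.resize(w.S * w.S);
  std::vector<char> present(w.S, 0);
  for (int i = 0; i < w.N; ++i) present[w.type[i]] = 1;
  for (int i = 0; i < w.S; ++i)
    for (int j = 0; j < w.S; ++j) {
      w.pair_a[i * w.S + j] = A(i, j);
      w.pair_g[i * w.S + j] = G(i, j);
      w.pair_rc[i * w.S + j] = RC(i, j);
      if (present[i] && present[j]) w.rc_max = std::max(w.rc_max, RC(i, j));
    }
  w.kBT = as<double>(world["kBT"]);
  w.dt = as<double>(world["dt"]);
  w.lambda = as<double>(world["lambda"]);
  if (world.containsElementNamed("bg_gamma") &&
      !Rf_isNull(world["bg_gamma"]))
    w.bg_gamma = as<double>(world["bg_gamma"]);

  List bonds = world["bonds"];
  if (bonds.containsElementNamed("wlc") && !Rf_isNull(bonds["wlc"])) {
    List wl = bonds["wlc"];
    IntegerMatrix ij = wl["ij"];
    for (int b = 0; b < ij.nrow(); ++b) {
      w.wlc_i.push_back(ij(b, 0) - 1);
      w.wlc_j.push_back(ij(b, 1) - 1);
    }
    NumericVector l0 = wl["l0"], lmax = wl["lmax"], kp = wl["kp"];
    w.wlc_l0.assign(l0.begin(), l0.end());
    w.wlc_lmax.assign(lmax.begin(), lmax.end());
    w.wlc_kp.assign(kp.begin(), kp.end());
    w.wlc_p = as<double>(wl["p"]);
    w.wlc_m = as<double>(wl["m"]);
    w.wlc_gamma = as<double>(wl["gamma"]);
    w.wlc_gamma_t = wl.containsElementNamed("gamma_t")
                        ? as<double>(wl["gamma_t"]) : 0.0;
  }
  if (bonds.containsElementNamed("harm") && !Rf_isNull(bonds["harm"])) {
    List hb = bonds["harm"];
    IntegerMatrix ij = hb["ij"];
    for (int b = 0; b < ij.nrow(); ++b) {
      w.hb_i.push_back(ij(b, 0) - 1);
      w.hb_j.push_back(ij(b, 1) - 1);
    }
    NumericVector r0 = hb["r0"], k = hb["k"];
    w.hb_r0.assign(r0.begin(), r0.end());
    w.hb_k.assign(k.begin(), k.end());
  }
  if (bonds.containsElementNamed("dyn") && !Rf_isNull(bonds["dyn"])) {
    List db = bonds["dyn"];
    IntegerMatrix ij = db["ij"];
    NumericVector r0 = db["r0"];
    IntegerVector kind = db["kind"];
    if (db.containsElementNamed("k")) {
      NumericVector kk = db["k"];
      w.dyn_k[0] = kk[0];
      w.dyn_k[1] = kk.size() > 1 ? kk[1] : kk[0];
    }  // else: spring constants come from the binding configuration
    for (int b = 0; b < ij.nrow(); ++b)
      w.dyn.push_back({ij(b, 0) - 1, ij(b, 1) - 1, kind[b], r0[b]});
  }
  if (bonds.containsElementNamed("angles") && !Rf_isNull(bonds["angles"])) {
    List an = bonds["angles"];
    IntegerMatrix ijk = an["ijk"];
    for (int a = 0; a < ijk.nrow(); ++a) {
      w.an_i.push_back(ijk(a, 0) - 1);
      w.an_j.push_back(ijk(a, 1) - 1);
      w.an_k.push_back(ijk(a, 2) - 1);
    }
    NumericVector t0 = an["theta0"], k = an["k"];
    w.an_t0.assign(t0.begin(), t0.end());
    w.an_kk.assign(k.begin(), k.end());
  }
  if (bonds.containsElementNamed("dihedrals") && !Rf_isNull(bonds["dihedrals"])) {
    List di = bonds["dihedrals"];
    IntegerMatrix ijkl = di["ijkl"];
    for (int a = 0; a < ijkl.nrow(); ++a) {
      w.di_i.push_back(ijkl(a, 0) - 1);
      w.di_j.push_back(ijkl(a, 1) - 1);
      w.di_k.push_back(ijkl(a, 2) - 1);
      w.di_l.push_back(ijkl(a, 3) - 1);
    }
    NumericVector t0 = di["theta0"], k = di["k"];
    w.di_t0.assign(t0.begin(), t0.end());
    w.di_kk.assign(k.begin(), k.end());
  }
  if (world.containsElementNamed("membrane") && !Rf_isNull(world["membrane"])) {
    List mem = world["membrane"];
    IntegerMatrix fc = mem["faces"];
    for (int f = 0; f < fc.nrow(); ++f) {
      w.fc_a.push_back(fc(f, 0) - 1);
      w.fc_b.push_back(fc(f, 1) - 1);
      w.fc_c.push_back(fc(f, 2) - 1);
    }
    NumericVector fa0 = mem["face_a0"];
    w.face_a0.assign(fa0.begin(), fa0.end());
    w.A0 = as<double>(mem["A0"]);
    w.V0 = as<double>(mem["V0"]);
    w.ka = as<double>(mem["ka"]);
    w.kv = as<double>(mem["kv"]);
    w.kd = as<double>(mem["kd"]);
    w.has_mem = true;
  }
  if (world.containsElementNamed("binding") && !Rf_isNull(world["binding"])) {
    List bi = world["binding"];
    w.has_bind = true;
    w.kon0 = as<double>(bi["kon0"]);
    w.koff0 = as<double>(bi["koff0"]);
    NumericVector so = bi["sigma_on"], sf = bi["sigma_off"];
    w.sig_on[0] = so[0]; w.sig_on[1] = so.size() > 1 ? so[1] : so[0];
    w.sig_off[0] = sf[0]; w.sig_off[1] = sf.size() > 1 ? sf[1] : sf[0];
    w.don = as<double>(bi["don"]);
    w.doff = as<double>(bi["doff"]);
    w.cand_l0 = as<double>(bi["l0"]);
    w.bind_every = as<int>(bi["every"]);
    w.dyn_k[0] = as<NumericVector>(bi["k"])[0];
    NumericVector kk = bi["k"];
    w.dyn_k[1] = kk.size() > 1 ? kk[1] : kk[0];
  }
  w.nlink0.assign(w.N, 0);
  w.nlink1.assign(w.N, 0);
  for (const auto& db : w.dyn) {
    if (db.kind == 0) { w.nlink0[db.i]++; w.nlink0[db.j]++; }
    else { w.nlink1[db.i]++; w.nlink1[db.j]++; }
  }
  if (world.containsElementNamed("aspiration") && !Rf_isNull(world["aspiration"])) {
    List as_ = world["aspiration"];
    w.has_asp = true;
    NumericVector p = as_["point"], u = as_["axis"];
    w.asp_p = Vec3(p[0], p[1], p[2]);
    Vec3 uu(u[0], u[1], u[2]);
    w.asp_u = uu * (1.0 / uu.norm());
    w.asp_f = as<double>(as_["magnitude"]);
    w.asp_rad = as<double>(as_["radius"]);
    w.asp_smin = as<double>(as_["smin"]);
    w.asp_smax = as<double>(as_["smax"]);
  }
  if (world.containsElementNamed("rupture") && !Rf_isNull(world["rupture"])) {
    List ru = world["rupture"];
    w.has_rupture = true;
    w.rupture_factor = as<double>(ru["factor"]);
  }
  if (world.containsElementNamed("drivers") && !Rf_isNull(world["drivers"])) {
    List drs = world["drivers"];
    for (int k = 0; k < drs.size(); ++k) {
      List d = drs[k];
      Driver dr;
      std::string mode = as<std::string>(d["mode"]);
      dr.idx = as_idx0(d["idx"]);
      if (mode == "translate") {
        dr.mode = 0;
        NumericVector v = d["vel"];
        dr.vel = Vec3(v[0], v[1], v[2]);
      } else if (mode == "oscillate") {
        dr.mode = 1;
        NumericVector ax = d["axis"];
        Vec3 a(ax[0], ax[1], ax[2]);
        dr.axis = a * (1.0 / a.norm());
        dr.amp = as<double>(d["amp"]);
        dr.freq = as<double>(d["freq"]);
      } else {
        stop("unknown driver mode '%s'", mode.c_str());
      }
      w.drivers.push_back(dr);
    }
  }
  w.group.assign(w.N, 0);
  if (world.containsElementNamed("measure_group") &&
      !Rf_isNull(world["measure_group"])) {
    IntegerVector g = world["measure_group"];
    for (int i = 0; i < w.N; ++i) {
      w.group[i] = g[i];
      w.ngroups = std::max(w.ngroups, g[i]);
    }
  }
  return w;
}

List energies_list(const Energies& E) {
  return List::create(
      _["pair"] = E.pair_cons, _["elastic"] = E.elastic, _["harm"] = E.harm,
      _["dyn"] = E.dynb, _["angle"] = E.angle, _["dihedral"] = E.dihedral,
      _["area_global"] = E.area_global, _["area_local"] = E.area_local,
      _["volume"] = E.volume, _["external"] = E.external,
      _["total"] = E.total());
}

// ------------------------------------------------------- binding kinetics

void binding_step(World& w, const std::vector<std::pair<int, int>>& nl,
                  double dt_elapsed, FastRng& rng,
                  std::vector<std::array<double, 5>>* events, double time) {
  auto unif = [](FastRng& r) { return r.unif(); };
  // unbinding: existing bonds at or beyond d_off may break (Bell rate, Eq 9)
  for (size_t b = 0; b < w.dyn.size();) {
    const DynBond& db = w.dyn[b];
    const double l = minimg(w, w.pos[db.i] - w.pos[db.j]).norm();
    bool broke = false;
    if (l >= w.doff) {
      const double dl = l - db.r0;
      const double koff = w.koff0 *
          std::exp(-w.sig_off[db.kind] * dl * dl / (2.0 * w.kBT));
      const double p = 1.0 - std::exp(-koff * dt_elapsed);
      if (unif(rng) < p) broke = true;
    }
    if (broke) {
      if (events)
        events->push_back({time, 0.0, (double)(db.i + 1), (double)(db.j + 1), l});
      if (db.kind == 0) { w.nlink0[db.i]--; w.nlink0[db.j]--; }
      else { w.nlink1[db.i]--; w.nlink1[db.j]--; }
      w.dyn[b] = w.dyn.back();
      w.dyn.pop_back();
    } else {
      ++b;
    }
  }
  // binding: eligible close pairs; capacities -- ACP <= 2 filament links,
  // filament particle <= 1 ACP link; membrane/filament links one-to-one
  for (const auto& pr : nl) {
    int i = pr.first, j = pr.second;
    int ti = w.type[i], tj = w.type[j];
    int kind = -1;
    if ((ti == 2 && tj == 1) || (ti == 1 && tj == 2)) kind = 0;
    else if ((ti == 0 && tj == 1) || (ti == 1 && tj == 0)) kind = 1;
    if (kind < 0) continue;
    if (ti != 2 && ti != 0) std::swap(i, j);  // i = acp/membrane, j = actin
    if (kind == 0) {
      if (w.nlink0[i] >= 2 || w.nlink0[j] >= 1) continue;
    } else {
      if (w.nlink1[i] >= 1 || w.nlink1[j] >= 1) continue;
    }
    const double l = minimg(w, w.pos[i] - w.pos[j]).norm();
    if (l >= w.don) continue;
    const double dl = l - w.cand_l0;
    const double kon = w.kon0 *
        std::exp(-w.sig_on[kind] * dl * dl / (2.0 * w.kBT));
    const double p = 1.0 - std::exp(-kon * dt_elapsed);
    if (unif(rng) < p) {
      w.dyn.push_back({i, j, kind, l});
      if (kind == 0) { w.nlink0[i]++; w.nlink0[j]++; }
      else { w.nlink1[i]++; w.nlink1[j]++; }
      if (events)
        events->push_back({time, 1.0, (double)(i + 1), (double)(j + 1), l});
    }
  }
}

}  // namespace

// ------------------------------------------------------------- R interface

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 LogicalVector periodic, double rmax) {
  World w;
  w.N = pos.nrow();
  w.pos.resize(w.N);
  for (int i = 0; i < w.N; ++i) w.pos[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
  for (int d = 0; d < 3; ++d) {
    w.box[d] = box[d];
    w.periodic[d] = periodic[d];
    if (w.periodic[d] && w.box[d] < 2.0 * rmax)
      stop("periodic box edge %d shorter than twice the cutoff", d + 1);
  }
  std::vector<std::pair<int, int>> nl;
  cell_pairs(w, rmax, nl);
  IntegerMatrix out(nl.size(), 2);
  for (size_t k = 0; k < nl.size(); ++k) {
    out(k, 0) = nl[k].first + 1;
    out(k, 1) = nl[k].second + 1;
  }
  return out;
}

// Deterministic forces and energies (no dissipative/random terms); the
// reference for finite-difference consistency checks.
// [[Rcpp::export]]
List cpp_forces_energy(List world) {
  World w = parse_world(world);
  std::vector<std::pair<int, int>> nl;
  cell_pairs(w, std::max(w.rc_max, 1e-6), nl);
  std::vector<Vec3> F(w.N);
  Energies E;
  compute_forces(w, nl, w.vel, F, false, nullptr, &E, true);
  NumericMatrix Fout(w.N, 3);
  for (int i = 0; i < w.N; ++i) {
    Fout(i, 0) = F[i].x; Fout(i, 1) = F[i].y; Fout(i, 2) = F[i].z;
  }
  return List::create(_["forces"] = Fout, _["energies"] = energies_list(E));
}

// One Monte-Carlo binding/unbinding sweep over the current configuration.
// [[Rcpp::export]]
List cpp_binding_sweep(List world, double dt_elapsed, int seed) {
  World w = parse_world(world);
  if (!w.has_bind) stop("world has no binding configuration");
  FastRng rng((uint64_t)seed * 2654435761u + 99u);
  double rmax = std::max(w.rc_max, w.don) + 1e-9;
  std::vector<std::pair<int, int>> nl;
  cell_pairs(w, rmax, nl);
  std::vector<std::array<double, 5>> ev;
  binding_step(w, nl, dt_elapsed, rng, &ev, 0.0);
  const int M = w.dyn.size();
  IntegerMatrix ij(M, 2);
  NumericVector r0(M);
  IntegerVector kind(M);
  for (int b = 0; b < M; ++b) {
    ij(b, 0) = w.dyn[b].i + 1;
    ij(b, 1) = w.dyn[b].j + 1;
    r0[b] = w.dyn[b].r0;
    kind[b] = w.dyn[b].kind;
  }
  return List::create(_["ij"] = ij, _["r0"] = r0, _["kind"] = kind);
}

// Greedy capacity-respecting matching of all eligible pairs within d_on:
// the long-time saturation limit of the stochastic binding rule.
// [[Rcpp::export]]
List cpp_bind_saturate(List world, int seed) {
  World w = parse_world(world);
  if (!w.has_bind) stop("world has no binding configuration");
  double rmax = std::max(w.rc_max, w.don) + 1e-9;
  std::vector<std::pair<int, int>> nl;
  cell_pairs(w, rmax, nl);
  std::mt19937_64 rng(seed);
  std::shuffle(nl.begin(), nl.end(), rng);  // keep std shuffle semantics
  for (const auto& pr : nl) {
    int i = pr.first, j = pr.second;
    int ti = w.type[i], tj = w.type[j];
    int kind = -1;
    if ((ti == 2 && tj == 1) || (ti == 1 && tj == 2)) kind = 0;
    else if ((ti == 0 && tj == 1) || (ti == 1 && tj == 0)) kind = 1;
    if (kind < 0) continue;
    if (ti != 2 && ti != 0) std::swap(i, j);
    if (kind == 0) {
      if (w.nlink0[i] >= 2 || w.nlink0[j] >= 1) continue;
    } else {
      if (w.nlink1[i] >= 1 || w.nlink1[j] >= 1) continue;
    }
    const double l = minimg(w, w.pos[i] - w.pos[j]).norm();
    if (l >= w.don) continue;
    w.dyn.push_back({i, j, kind, l});
    if (kind == 0) { w.nlink0[i]++; w.nlink0[j]++; }
    else { w.nlink1[i]++; w.nlink1[j]++; }
  }
  const int M = w.dyn.size();
  IntegerMatrix ij(M, 2);
  NumericVector r0(M);
  IntegerVector kind(M);
  for (int b = 0; b < M; ++b) {
    ij(b, 0) = w.dyn[b].i + 1;
    ij(b, 1) = w.dyn[b].j + 1;
    r0[b] = w.dyn[b].r0;
    kind[b] = w.dyn[b].kind;
  }
  return List::create(_["ij"] = ij, _["r0"] = r0, _["kind"] = kind);
}

// Integrate nsteps of DPD-modified velocity-Verlet.  Returns final state,
// tracked unwrapped trajectory frames, observables, dynamic bond table and
// (if the halt rule fired) the rupture event.
// [[Rcpp::export]]
List cpp_run(List world, int nsteps, int seed, int sample_every,
             IntegerVector track, int nl_every = 5, double skin = 0.3,
             bool log_bond_events = false) {
  World w = parse_world(world);
  FastRng rng((uint64_t)seed * 2654435761u + 12345u);
  const double rmax0 = std::max(w.rc_max, w.has_bind ? w.don : 0.0);
  const double rmax = rmax0 + skin;
  std::vector<std::pair<int, int>> nl;
  std::vector<Vec3> F(w.N), Fnew(w.N), vtil(w.N);
  std::vector<int> trk = as_idx0(track);

  // drivers: record unwrapped base positions
  for (auto& dr : w.drivers) {
    dr.base.resize(dr.idx.size());
    for (size_t k = 0; k < dr.idx.size(); ++k) dr.base[k] = w.pos[dr.idx[k]];
  }

  const int nsample = (sample_every > 0) ? nsteps / sample_every : 0;
  const int obs_ncol = 8 + 3 * w.ngroups;
  NumericMatrix obs(nsample, obs_ncol);
  NumericVector frames(
      nsample > 0 ? (R_xlen_t)nsample * trk.size() * 3 : 0);
  std::vector<Vec3> gacc(w.ngroups);
  int gacc_n = 0;

  std::vector<std::array<double, 5>> events;
  List rupture = R_NilValue;

  cell_pairs(w, rmax, nl);
  compute_forces(w, nl, w.vel, F, true, &rng, nullptr);

  int isample = 0;
  int steps_done = 0;
  for (int step = 0; step < nsteps; ++step) {
    const double t = (step + 1) * w.dt;
    // position update + velocity prediction
    for (int i = 0; i < w.N; ++i) {
      if (w.frozen[i]) { vtil[i] = w.vel[i]; continue; }
      w.pos[i] += w.vel[i] * w.dt + F[i] * (0.5 * w.dt * w.dt);
      vtil[i] = w.vel[i] + F[i] * (w.lambda * w.dt);
    }
    // prescribed motion
    for (auto& dr : w.drivers) {
      if (dr.mode == 0) {
        for (size_t k = 0; k < dr.idx.size(); ++k) {
          const int i = dr.idx[k];
          w.pos[i] += dr.vel * w.dt;
          w.vel[i] = dr.vel;
          vtil[i] = dr.vel;
        }
      } else {
        const double ph = 2.0 * M_PI * dr.freq * t;
        const double disp = dr.amp * std::sin(ph);
        const double v = dr.amp * 2.0 * M_PI * dr.freq * std::cos(ph);
        for (size_t k = 0; k < dr.idx.size(); ++k) {
          const int i = dr.idx[k];
          w.pos[i] = dr.base[k] + dr.axis * disp;
          w.vel[i] = dr.axis * v;
          vtil[i] = w.vel[i];
        }
      }
    }
    // periodic wrap with image bookkeeping
    for (int i = 0; i < w.N; ++i) {
      if (w.periodic[0]) {
        double nx = wrap1(w.pos[i].x, w.box[0]);
        w.img_x[i] += (int)std::lround((w.pos[i].x - nx) / w.box[0]);
        w.pos[i].x = nx;
      }
      if (w.periodic[1]) {
        double ny = wrap1(w.pos[i].y, w.box[1]);
        w.img_y[i] += (int)std::lround((w.pos[i].y - ny) / w.box[1]);
        w.pos[i].y = ny;
      }
      if (w.periodic[2]) {
        double nz = wrap1(w.pos[i].z, w.box[2]);
        w.img_z[i] += (int)std::lround((w.pos[i].z - nz) / w.box[2]);
        w.pos[i].z = nz;
      }
    }
    if ((step + 1) % nl_every == 0 || step == 0) {
      nl.clear();
      cell_pairs(w, rmax, nl);
    }
    compute_forces(w, nl, vtil, Fnew, true, &rng, nullptr, false,
                   (step + 1) % kBathStride == 0);
    for (int i = 0; i < w.N; ++i) {
      if (w.frozen[i]) continue;
      w.vel[i] += (F[i] + Fnew[i]) * (0.5 * w.dt);
      if (!std::isfinite(w.pos[i].x) || !std::isfinite(w.vel[i].x) ||
          !std::isfinite(w.pos[i].y) || !std::isfinite(w.vel[i].y) ||
          !std::isfinite(w.pos[i].z) || !std::isfinite(w.vel[i].z))
        stop("non-finite state for particle %d at step %d", i + 1, step + 1);
    }
    std::swap(F, Fnew);
    steps_done = step + 1;

    // accumulate group loads (force exerted on the group by everything
    // else); reported as the average over each sampling interval
    if (w.ngroups > 0) {
      for (int i = 0; i < w.N; ++i)
        if (w.group[i] > 0) gacc[w.group[i] - 1] += F[i];
      gacc_n++;
    }

    // Bell-model binding/unbinding
    if (w.has_bind && (step + 1) % w.bind_every == 0)
      binding_step(w, nl, w.bind_every * w.dt, rng,
                   log_bond_events ? &events : nullptr, t);

    // membrane rupture halt rule
    if (w.has_rupture) {
      bool halted = false;
      for (size_t b = 0; b < w.wlc_i.size(); ++b) {
        const double l =
            minimg(w, w.pos[w.wlc_i[b]] - w.pos[w.wlc_j[b]]).norm();
        if (l > w.rupture_factor * w.wlc_l0[b]) {
          rupture = List::create(
              _["step"] = step + 1, _["time"] = t, _["bond"] = (int)b + 1,
              _["length"] = l, _["l0"] = w.wlc_l0[b]);
          halted = true;
          break;
        }
      }
      if (halted) break;
    }

    if (sample_every > 0 && (step + 1) % sample_every == 0 &&
        isample < nsample) {
      double ke = 0;
      int nfree = 0;
      Vec3 mom;
      for (int i = 0; i < w.N; ++i) {
        if (w.frozen[i]) continue;
        ke += w.vel[i].norm2();
        mom += w.vel[i];
        nfree++;
      }
      obs(isample, 0) = t;
      obs(isample, 1) = nfree > 0 ? ke / (3.0 * nfree) : NA_REAL;
      obs(isample, 2) = mom.x;
      obs(isample, 3) = mom.y;
      obs(isample, 4) = mom.z;
      double disp = NA_REAL;
      if (!w.drivers.empty()) {
        const Driver& dr = w.drivers[0];
        disp = (dr.mode == 1) ? dr.amp * std::sin(2.0 * M_PI * dr.freq * t)
                              : dr.vel.norm() * t;
      }
      obs(isample, 5) = disp;
      obs(isample, 6) = (double)w.dyn.size();
      obs(isample, 7) = 0.0;
      for (int g = 0; g < w.ngroups; ++g) {
        const double inv = gacc_n > 0 ? 1.0 / gacc_n : 0.0;
        obs(isample, 8 + 3 * g) = gacc[g].x * inv;
        obs(isample, 8 + 3 * g + 1) = gacc[g].y * inv;
        obs(isample, 8 + 3 * g + 2) = gacc[g].z * inv;
        gacc[g] = Vec3();
      }
      gacc_n = 0;
      for (size_t k = 0; k < trk.size(); ++k) {
        const int i = trk[k];
        const Vec3 u(w.pos[i].x + w.img_x[i] * w.box[0],
                     w.pos[i].y + w.img_y[i] * w.box[1],
                     w.pos[i].z + w.img_z[i] * w.box[2]);
        const R_xlen_t base =
            (R_xlen_t)isample + (R_xlen_t)nsample * (R_xlen_t)k;
        frames[base] = u.x;
        frames[base + (R_xlen_t)nsample * trk.size()] = u.y;
        frames[base + 2 * (R_xlen_t)nsample * trk.size()] = u.z;
      }
      isample++;
    }
  }

  NumericMatrix pos_out(w.N, 3), vel_out(w.N, 3);
  IntegerMatrix img_out(w.N, 3);
  for (int i = 0; i < w.N; ++i) {
    pos_out(i, 0) = w.pos[i].x; pos_out(i, 1) = w.pos[i].y; pos_out(i, 2) = w.pos[i].z;
    vel_out(i, 0) = w.vel[i].x; vel_out(i, 1) = w.vel[i].y; vel_out(i, 2) = w.vel[i].z;
    img_out(i, 0) = w.img_x[i]; img_out(i, 1) = w.img_y[i]; img_out(i, 2) = w.img_z[i];
  }
  const int M = w.dyn.size();
  IntegerMatrix dij(M, 2);
  NumericVector dr0(M);
  IntegerVector dkind(M);
  for (int b = 0; b < M; ++b) {
    dij(b, 0) = w.dyn[b].i + 1;
    dij(b, 1) = w.dyn[b].j + 1;
    dr0[b] = w.dyn[b].r0;
    dkind[b] = w.dyn[b].kind;
  }
  NumericMatrix ev(events.size(), 5);
  for (size_t e = 0; e < events.size(); ++e)
    for (int c = 0; c < 5; ++c) ev(e, c) = events[e][c];

  frames.attr("dim") =
      IntegerVector::create(nsample, (int)trk.size(), 3);
  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["img"] = img_out,
      _["obs"] = obs, _["frames"] = frames, _["nsample"] = isample,
      _["steps_done"] = steps_done,
      _["dyn"] = List::create(_["ij"] = dij, _["r0"] = dr0, _["kind"] = dkind),
      _["rupture"] = rupture, _["events"] = ev);
}

// Multi-time-origin mean-square displacement of unwrapped trajectories.
// traj: nsample x ntrack x 3 array; lags: vector of frame lags (>= 1).
// [[Rcpp::export]]
NumericVector cpp_msd(NumericVector traj, IntegerVector lags) {
  IntegerVector dim = traj.attr("dim");
  const int T = dim[0], P = dim[1];
  NumericVector out(lags.size());
  for (int k = 0; k < lags.size(); ++k) {
    const int lag = lags[k];
    if (lag >= T) { out[k] = NA_REAL; continue; }
    double acc = 0;
    long n = 0;
    for (int p = 0; p < P; ++p) {
      const R_xlen_t off = (R_xlen_t)T * p;
      const R_xlen_t offy = off + (R_xlen_t)T * P;
      const R_xlen_t offz = off + 2 * (R_xlen_t)T * P;
      for (int t0 = 0; t0 + lag < T; ++t0) {
        const double dx = traj[off + t0 + lag] - traj[off + t0];
        const double dy = traj[offy + t0 + lag] - traj[offy + t0];
        const double dz = traj[offz + t0 + lag] - traj[offz + t0];
        acc += dx * dx + dy * dy + dz * dz;
        n++;
      }
    }
    out[k] = acc / n;
  }
  return out;
}
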