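// Coarse-grained engine: bonded terms, WCA excluded volume, registry- and
// orientation-aware sticky attraction, steepest-descent minimization,
// BAOAB Langevin dynamics with Verlet neighbour lists, and per-frame
// segment contact maps for trajectory analysis.
//
// Conventions: positions in nm (kept UNWRAPPED; minimum image applied only
// to nonbonded pair distances), time ps, energy kJ/mol, mass amu. kT is
// passed in already scaled by the force field's temperature_scale.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <map>
#include <utility>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// splitmix64 -> xoshiro256++ with Box-Muller; deterministic across platforms.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
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
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // Marsaglia polar method with spare caching (no trig calls)
  double spare = 0;
  bool has_spare = false;
  inline double gauss() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double v1, v2, s;
    do {
      v1 = 2.0 * unif() - 1.0;
      v2 = 2.0 * unif() - 1.0;
      s = v1 * v1 + v2 * v2;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v2 * m;
    has_spare = true;
    return v1 * m;
  }
};

// ----------------------------------------------------------- topology ----
struct Topo {
  int N = 0, nseg = 0, ntype = 0, nchain = 0;
  std::vector<int> chain, seg, type, reg, clen;   // per bead (1-based ids)
  std::vector<int> b_i, b_j;                      // bonds (0-based beads)
  std::vector<int> a_i, a_j, a_k;                 // angles
  std::vector<int> pair_code;                     // ntype^2: 0 none 1 par 2 anti
  std::vector<double> pair_strength;
  std::vector<int> seg_first, seg_last, seg_type; // per segment (1-based idx)
  std::vector<std::vector<int>> excl;             // bonded exclusions
};

static Topo read_topo(const List& tl) {
  Topo t;
  IntegerVector chain = tl["chain"], seg = tl["seg"], type = tl["type"],
                reg = tl["reg"], clen = tl["clen"];
  t.N = chain.size();
  t.chain.assign(chain.begin(), chain.end());
  t.seg.assign(seg.begin(), seg.end());
  t.type.assign(type.begin(), type.end());
  t.reg.assign(reg.begin(), reg.end());
  t.clen.assign(clen.begin(), clen.end());
  IntegerMatrix bonds = tl["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    t.b_i.push_back(bonds(b, 0) - 1);
    t.b_j.push_back(bonds(b, 1) - 1);
  }
  IntegerMatrix ang = tl["angles"];
  for (int a = 0; a < ang.nrow(); ++a) {
    t.a_i.push_back(ang(a, 0) - 1);
    t.a_j.push_back(ang(a, 1) - 1);
    t.a_k.push_back(ang(a, 2) - 1);
  }
  IntegerMatrix pc = tl["pair_code"];
  NumericMatrix ps = tl["pair_strength"];
  t.ntype = pc.nrow();
  t.pair_code.resize(t.ntype * t.ntype);
  t.pair_strength.resize(t.ntype * t.ntype);
  for (int i = 0; i < t.ntype; ++i)
    for (int j = 0; j < t.ntype; ++j) {
      t.pair_code[i * t.ntype + j] = pc(i, j);
      t.pair_strength[i * t.ntype + j] = ps(i, j);
    }
  t.nseg = 0;
  t.nchain = 0;
  for (int i = 0; i < t.N; ++i) {
    if (t.seg[i] > t.nseg) t.nseg = t.seg[i];
    if (t.chain[i] > t.nchain) t.nchain = t.chain[i];
  }
  t.seg_first.assign(t.nseg + 1, -1);
  t.seg_last.assign(t.nseg + 1, -1);
  t.seg_type.assign(t.nseg + 1, 0);
  for (int i = 0; i < t.N; ++i) {
    int s = t.seg[i];
    if (t.seg_first[s] < 0) t.seg_first[s] = i;
    t.seg_last[s] = i;
    t.seg_type[s] = t.type[i];
  }
  t.excl.assign(t.N, {});
  for (size_t b = 0; b < t.b_i.size(); ++b) {
    t.excl[t.b_i[b]].push_back(t.b_j[b]);
    t.excl[t.b_j[b]].push_back(t.b_i[b]);
  }
  return t;
}

struct Par {
  double sigma_sticky, epsilon_sticky, cutoff_sticky;
  double sigma_rep, epsilon_rep, cutoff_rep;
  double sigma_fat, cutoff_fat;   // steric diameter of non-partner coils
  double bond_r0, bond_k, angle_k;
  double mass, r_floor, gate_lo, gate_hi, skin;
  double sigma_ex, epsilon_ex, cutoff_ex;   // competitor exclusion (WCA)
  double sticky_shift; // unscaled LJ value at the sticky cutoff
};

static Par read_par(const List& pl) {
  Par p;
  p.sigma_sticky = as<double>(pl["sigma_sticky"]);
  p.epsilon_sticky = as<double>(pl["epsilon_sticky"]);
  p.cutoff_sticky = as<double>(pl["cutoff_sticky"]);
  p.sigma_rep = as<double>(pl["sigma_rep"]);
  p.epsilon_rep = as<double>(pl["epsilon_rep"]);
  p.cutoff_rep = as<double>(pl["cutoff_rep"]);
  p.bond_r0 = as<double>(pl["bond_r0"]);
  p.bond_k = as<double>(pl["bond_k"]);
  p.angle_k = as<double>(pl["angle_k"]);
  p.mass = as<double>(pl["mass"]);
  p.r_floor = as<double>(pl["r_floor"]);
  p.gate_lo = as<double>(pl["gate_lo"]);
  p.gate_hi = as<double>(pl["gate_hi"]);
  p.skin = as<double>(pl["skin"]);
  p.sigma_fat = as<double>(pl["sigma_fat"]);
  p.cutoff_fat = std::pow(2.0, 1.0 / 6.0) * p.sigma_fat;
  p.sigma_ex = as<double>(pl["sigma_ex"]);
  p.epsilon_ex = as<double>(pl["epsilon_ex"]);
  p.cutoff_ex = 1.3 * p.sigma_ex;
  double sr6 = std::pow(p.sigma_sticky / p.cutoff_sticky, 6.0);
  p.sticky_shift = 4.0 * p.epsilon_sticky * (sr6 * sr6 - sr6);
  return p;
}

static inline void min_image(double* d, const double* box) {
  for (int k = 0; k < 3; ++k) {
    if (box[k] > 0) d[k] -= box[k] * std::round(d[k] / box[k]);
  }
}

// Registry complementarity under the pair rule's orientation.
static inline bool complementary(const Topo& t, int i, int j, int code) {
  if (code == 1) return t.reg[i] == t.reg[j];
  if (code == 2)
    return t.clen[i] == t.clen[j] && t.reg[j] == t.clen[i] + 1 - t.reg[i];
  return false;
}

// ------------------------------------------------------ neighbour list ----
struct Pair {
  int i, j;
  int8_t code;       // 1 parallel sticky, 2 antiparallel, 3 competitor excl.
  double strength;
};

// Split Verlet lists: short-range excluded-volume pairs (thin backbone or
// fat non-partner-coil diameter) and (sparse) registry-complementary
// sticky pairs, which carry the larger cutoff.
struct RepPair {
  int i, j;
  int8_t fat;
};

struct NList {
  std::vector<RepPair> rep_pairs;
  std::vector<Pair> sticky_pairs;
  std::vector<Pair> static_sticky;  // all registry-eligible pairs (static)
  std::vector<double> x0; // positions at build time
  bool built = false;
  bool static_done = false;
};

// non-partner coil beads (segment types that do not form a designed dimer
// pair) repel at the steric diameter of a helix pair
static inline bool fat_pair(const Topo& t, int i, int j) {
  return t.type[i] > 0 && t.type[j] > 0 && t.seg[i] != t.seg[j] &&
         t.pair_code[(t.type[i] - 1) * t.ntype + (t.type[j] - 1)] == 0;
}

static bool excluded(const Topo& t, int i, int j) {
  for (int e : t.excl[i]) if (e == j) return true;
  return false;
}

static void classify_pair(const Topo& t, int i, int j, int8_t& code,
                          double& strength) {
  code = 0;
  strength = 0;
  if (t.type[i] > 0 && t.type[j] > 0 && t.seg[i] != t.seg[j]) {
    int c = t.pair_code[(t.type[i] - 1) * t.ntype + (t.type[j] - 1)];
    if (c > 0 && complementary(t, i, j, c)) {
      double s = t.pair_strength[(t.type[i] - 1) * t.ntype + (t.type[j] - 1)];
      if (s > 0) {
        code = (int8_t)c;
        strength = s;
        return;
      }
    }
    // competitor exclusion: beads of the same coil type at the same
    // registry index bind the same target bead and repel softly, which
    // keeps the coiled-coil interface effectively one-to-one. For
    // homodimeric types the exclusion is gated on parallel axis alignment
    // (code 4): a bound antiparallel homodimer has anti-aligned helices
    // and same-registry beads legitimately close near the rod centre,
    // while a third-party attacker approaches parallel to the helix it
    // would displace.
    if (t.type[i] == t.type[j] && t.reg[i] == t.reg[j]) {
      bool homodimer =
          t.pair_code[(t.type[i] - 1) * t.ntype + (t.type[i] - 1)] > 0;
      code = homodimer ? 4 : 3;
      strength = 1.0;
    }
  }
}

static void build_nlist(const std::vector<double>& x, const double* box,
                        const Topo& t, const Par& p, NList& nl) {
  double rlist_st = p.cutoff_sticky + p.skin;
  double rlist_rep = p.cutoff_rep + p.skin;
  double rlist_fat = p.cutoff_fat + p.skin;
  nl.rep_pairs.clear();
  nl.sticky_pairs.clear();
  nl.x0 = x;
  nl.built = true;
  int N = t.N;
  double r2_st = rlist_st * rlist_st;
  double r2_rep = rlist_rep * rlist_rep;
  double r2_fat = rlist_fat * rlist_fat;
  double ib[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};

  // registry-eligible (sticky / competitor) pairs are static and sparse:
  // enumerate them once, then distance-filter at every rebuild
  if (!nl.static_done) {
    nl.static_done = true;
    for (int i = 0; i < N; ++i) {
      if (t.type[i] <= 0) continue;
      for (int j = i + 1; j < N; ++j) {
        if (t.type[j] <= 0) continue;
        if (t.chain[i] == t.chain[j] && excluded(t, i, j)) continue;
        Pair pr;
        pr.i = i;
        pr.j = j;
        classify_pair(t, i, j, pr.code, pr.strength);
        if (pr.code > 0) nl.static_sticky.push_back(pr);
      }
    }
  }
  for (const Pair& pr : nl.static_sticky) {
    double d0 = x[3 * pr.i] - x[3 * pr.j];
    double d1 = x[3 * pr.i + 1] - x[3 * pr.j + 1];
    double d2 = x[3 * pr.i + 2] - x[3 * pr.j + 2];
    d0 -= box[0] * (double)(long long)(d0 * ib[0] + (d0 >= 0 ? 0.5 : -0.5));
    d1 -= box[1] * (double)(long long)(d1 * ib[1] + (d1 >= 0 ? 0.5 : -0.5));
    d2 -= box[2] * (double)(long long)(d2 * ib[2] + (d2 >= 0 ? 0.5 : -0.5));
    if (d0 * d0 + d1 * d1 + d2 * d2 < r2_st) nl.sticky_pairs.push_back(pr);
  }

  int nc[3];
  bool cells_ok = true;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(box[k] / rlist_fat);
    if (nc[k] < 3) cells_ok = false;
  }

  auto try_add = [&](int i, int j) {
    double d0 = x[3 * i] - x[3 * j];
    double d1 = x[3 * i + 1] - x[3 * j + 1];
    double d2 = x[3 * i + 2] - x[3 * j + 2];
    d0 -= box[0] * (double)(long long)(d0 * ib[0] + (d0 >= 0 ? 0.5 : -0.5));
    d1 -= box[1] * (double)(long long)(d1 * ib[1] + (d1 >= 0 ? 0.5 : -0.5));
    d2 -= box[2] * (double)(long long)(d2 * ib[2] + (d2 >= 0 ? 0.5 : -0.5));
    double r2 = d0 * d0 + d1 * d1 + d2 * d2;
    if (r2 >= r2_fat) return;
    if (t.chain[i] == t.chain[j] && excluded(t, i, j)) return;
    if (fat_pair(t, i, j)) {
      nl.rep_pairs.push_back({i, j, 1});
    } else if (r2 < r2_rep) {
      nl.rep_pairs.push_back({i, j, 0});
    }
  };

  if (!cells_ok) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) try_add(i, j);
    return;
  }

  // cell list on wrapped coordinates
  int ncells = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncells, -1), nxt(N, -1), cidx(N);
  for (int i = 0; i < N; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = x[3 * i + k] - box[k] * std::floor(x[3 * i + k] / box[k]);
      if (w < 0) w += box[k];
      if (w >= box[k]) w = 0;
      c[k] = (int)(w / box[k] * nc[k]);
      if (c[k] >= nc[k]) c[k] = nc[k] - 1;
    }
    int cc = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cidx[i] = cc;
    nxt[i] = head[cc];
    head[cc] = i;
  }
  // half stencil (13 neighbours) + self cell
  static const int st[13][3] = {
      {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
      {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
      {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int cc = (cz * nc[1] + cy) * nc[0] + cx;
        for (int i = head[cc]; i >= 0; i = nxt[i])
          for (int j = nxt[i]; j >= 0; j = nxt[j]) try_add(i, j);
        for (int s = 0; s < 13; ++s) {
          int ox = (cx + st[s][0] + nc[0]) % nc[0];
          int oy = (cy + st[s][1] + nc[1]) % nc[1];
          int oz = (cz + st[s][2] + nc[2]) % nc[2];
          int oc = (oz * nc[1] + oy) * nc[0] + ox;
          if (oc == cc) continue;
          for (int i = head[cc]; i >= 0; i = nxt[i])
            for (int j = head[oc]; j >= 0; j = nxt[j]) try_add(i, j);
        }
      }
}

static bool nlist_stale(const std::vector<double>& x, const NList& nl,
                        const Par& p) {
  if (!nl.built) return true;
  double lim2 = (p.skin * 0.5) * (p.skin * 0.5);
  for (size_t i = 0; i < x.size(); i += 3) {
    double dx = x[i] - nl.x0[i];
    double dy = x[i + 1] - nl.x0[i + 1];
    double dz = x[i + 2] - nl.x0[i + 2];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// --------------------------------------------------------- smoothstep ----
static inline double smoothstep(double x, double lo, double hi, double& deriv) {
  if (x <= lo) { deriv = 0; return 0; }
  if (x >= hi) { deriv = 0; return 1; }
  double u = (x - lo) / (hi - lo);
  deriv = 6.0 * u * (1.0 - u) / (hi - lo);
  return u * u * (3.0 - 2.0 * u);
}

// ------------------------------------------------------------- forces ----
struct EComp {
  double bond = 0, angle = 0, rep = 0, sticky = 0;
  double total() const { return bond + angle + rep + sticky; }
};

// Segment axes for the orientation gate (raw unwrapped coordinates).
static void seg_axes(const std::vector<double>& x, const Topo& t,
                     std::vector<double>& u, std::vector<double>& vnorm) {
  u.assign(3 * (t.nseg + 1), 0.0);
  vnorm.assign(t.nseg + 1, 0.0);
  for (int s = 1; s <= t.nseg; ++s) {
    if (t.seg_type[s] <= 0) continue;
    int a = t.seg_first[s], b = t.seg_last[s];
    double v[3] = {x[3 * b] - x[3 * a], x[3 * b + 1] - x[3 * a + 1],
                   x[3 * b + 2] - x[3 * a + 2]};
    double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (n < 1e-12) n = 1e-12;
    vnorm[s] = n;
    for (int k = 0; k < 3; ++k) u[3 * s + k] = v[k] / n;
  }
}

static EComp compute_forces(const std::vector<double>& x, const double* box,
                            const Topo& t, const Par& p, const NList& nl,
                            std::vector<double>& f) {
  EComp e;
  f.assign(3 * t.N, 0.0);

  // bonds (direct differences; chains stay unwrapped)
  for (size_t b = 0; b < t.b_i.size(); ++b) {
    int i = t.b_i[b], j = t.b_j[b];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r < 1e-9) r = 1e-9;
    double dr = r - p.bond_r0;
    e.bond += 0.5 * p.bond_k * dr * dr;
    double fmag = -p.bond_k * dr / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += fmag * d[k];
      f[3 * j + k] -= fmag * d[k];
    }
  }

  // rod-stiffening bending term on coil-internal triplets:
  // E = k_angle * (1 + cos theta); harmonic in the deviation from 180 deg
  // near the minimum with the same constant, and force-regular at theta = pi.
  for (size_t a = 0; a < t.a_i.size(); ++a) {
    int i = t.a_i[a], j = t.a_j[a], k3 = t.a_k[a];
    double va[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                    x[3 * i + 2] - x[3 * j + 2]};
    double vb[3] = {x[3 * k3] - x[3 * j], x[3 * k3 + 1] - x[3 * j + 1],
                    x[3 * k3 + 2] - x[3 * j + 2]};
    double na = std::sqrt(va[0] * va[0] + va[1] * va[1] + va[2] * va[2]);
    double nb = std::sqrt(vb[0] * vb[0] + vb[1] * vb[1] + vb[2] * vb[2]);
    if (na < 1e-9) na = 1e-9;
    if (nb < 1e-9) nb = 1e-9;
    double dot = va[0] * vb[0] + va[1] * vb[1] + va[2] * vb[2];
    double ct = dot / (na * nb);
    if (ct > 1) ct = 1;
    if (ct < -1) ct = -1;
    e.angle += p.angle_k * (1.0 + ct);
    double dEdc = p.angle_k;
    for (int k = 0; k < 3; ++k) {
      double ga = (vb[k] / (na * nb)) - ct * va[k] / (na * na);
      double gb = (va[k] / (na * nb)) - ct * vb[k] / (nb * nb);
      f[3 * i + k] -= dEdc * ga;
      f[3 * k3 + k] -= dEdc * gb;
      f[3 * j + k] += dEdc * (ga + gb);
    }
  }

  // nonbonded
  std::vector<double> u, vnorm;
  seg_axes(x, t, u, vnorm);
  std::map<std::pair<int, int>, double> gate_sum; // (seg_a,seg_b) -> dE/dd
  double rc_rep2 = p.cutoff_rep * p.cutoff_rep;
  double rc_st2 = p.cutoff_sticky * p.cutoff_sticky;
  double ib[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};

  double rc_fat2 = p.cutoff_fat * p.cutoff_fat;
  for (const auto& pr : nl.rep_pairs) {
    int i = pr.i, j = pr.j;
    double d0 = x[3 * i] - x[3 * j];
    double d1 = x[3 * i + 1] - x[3 * j + 1];
    double d2 = x[3 * i + 2] - x[3 * j + 2];
    d0 -= box[0] * (double)(long long)(d0 * ib[0] + (d0 >= 0 ? 0.5 : -0.5));
    d1 -= box[1] * (double)(long long)(d1 * ib[1] + (d1 >= 0 ? 0.5 : -0.5));
    d2 -= box[2] * (double)(long long)(d2 * ib[2] + (d2 >= 0 ? 0.5 : -0.5));
    double r2 = d0 * d0 + d1 * d1 + d2 * d2;
    double sig = pr.fat ? p.sigma_fat : p.sigma_rep;
    double rc2 = pr.fat ? rc_fat2 : rc_rep2;
    if (r2 >= rc2) continue;
    double r = std::sqrt(r2);
    double re = r < p.r_floor ? p.r_floor : r;
    double q = sig / re, q2 = q * q;
    double sr6 = q2 * q2 * q2;
    e.rep += 4.0 * p.epsilon_rep * (sr6 * sr6 - sr6) + p.epsilon_rep;
    double fmag = 24.0 * p.epsilon_rep * (2.0 * sr6 * sr6 - sr6) / re;
    if (r > 1e-9) {
      double fr = fmag / r;
      f[3 * i] += fr * d0;
      f[3 * i + 1] += fr * d1;
      f[3 * i + 2] += fr * d2;
      f[3 * j] -= fr * d0;
      f[3 * j + 1] -= fr * d1;
      f[3 * j + 2] -= fr * d2;
    }
  }

  double rc_ex2 = p.cutoff_ex * p.cutoff_ex;
  for (const Pair& pr : nl.sticky_pairs) {
    int i = pr.i, j = pr.j;
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    min_image(d, box);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (pr.code >= 3) {
      if (r2 < rc_ex2) {
        // bounded soft-core: eps_ex (1 + cos(pi r / rc)); max 2 eps_ex,
        // forces and gate gradients stay finite at any overlap
        double r = std::sqrt(r2);
        double arg = 3.14159265358979 * r / p.cutoff_ex;
        double w = p.epsilon_ex * (1.0 + std::cos(arg));
        double dwdr = -p.epsilon_ex * 3.14159265358979 / p.cutoff_ex *
                      std::sin(arg);
        double g = 1.0, gd = 0.0;
        int sa = 0, sb = 0;
        if (pr.code == 4) {
          sa = t.seg[i];
          sb = t.seg[j];
          double dd = u[3 * sa] * u[3 * sb] + u[3 * sa + 1] * u[3 * sb + 1] +
                      u[3 * sa + 2] * u[3 * sb + 2];
          g = smoothstep(dd, p.gate_lo, p.gate_hi, gd);
        }
        if (g > 0 || gd != 0) {
          e.rep += g * w;
          if (g > 0 && r > 1e-9) {
            double fr = -g * dwdr / r;
            for (int k = 0; k < 3; ++k) {
              f[3 * i + k] += fr * d[k];
              f[3 * j + k] -= fr * d[k];
            }
          }
          if (gd != 0 && w != 0) {
            auto key = sa < sb ? std::make_pair(sa, sb)
                               : std::make_pair(sb, sa);
            gate_sum[key] += gd * w;
          }
        }
      }
      continue;
    }
    if (r2 < rc_st2) {
      double r = std::sqrt(r2);
      bool capped = r < p.r_floor;
      double re = capped ? p.r_floor : r;
      int sa = t.seg[i], sb = t.seg[j];
      double dd = u[3 * sa] * u[3 * sb] + u[3 * sa + 1] * u[3 * sb + 1] +
                  u[3 * sa + 2] * u[3 * sb + 2];
      double gd, g;
      if (pr.code == 1)
        g = smoothstep(dd, p.gate_lo, p.gate_hi, gd);
      else {
        g = smoothstep(-dd, p.gate_lo, p.gate_hi, gd);
        gd = -gd;
      }
      if (g > 0 || gd != 0) {
        double q = p.sigma_sticky / re, q2 = q * q;
        double sr6 = q2 * q2 * q2;
        double w = pr.strength *
                   (4.0 * p.epsilon_sticky * (sr6 * sr6 - sr6) - p.sticky_shift);
        e.sticky += g * w;
        if (g > 0) {
          double dwdr =
              pr.strength * (-24.0 * p.epsilon_sticky *
                             (2.0 * sr6 * sr6 - sr6) / re);
          if (!capped && r > 1e-9) {
            double fmag = -g * dwdr / r;
            for (int k = 0; k < 3; ++k) {
              f[3 * i + k] += fmag * d[k];
              f[3 * j + k] -= fmag * d[k];
            }
          }
        }
        if (gd != 0 && w != 0) {
          auto key = sa < sb ? std::make_pair(sa, sb) : std::make_pair(sb, sa);
          // store signed contribution: dE/dd = gd * w for this pair
          gate_sum[key] += gd * w;
        }
      }
    }
  }

  // orientation-gate gradient through the segment end beads
  for (auto& kv : gate_sum) {
    int sa = kv.first.first, sb = kv.first.second;
    double dEdd = kv.second;
    int fa = t.seg_first[sa], la = t.seg_last[sa];
    int fb = t.seg_first[sb], lb = t.seg_last[sb];
    double dot_ab = u[3 * sa + 0] * u[3 * sb + 0] +
                    u[3 * sa + 1] * u[3 * sb + 1] +
                    u[3 * sa + 2] * u[3 * sb + 2];
    double da[3], db[3];
    for (int k = 0; k < 3; ++k) {
      da[k] = (u[3 * sb + k] - dot_ab * u[3 * sa + k]) / vnorm[sa];
      db[k] = (u[3 * sa + k] - dot_ab * u[3 * sb + k]) / vnorm[sb];
      f[3 * la + k] -= dEdd * da[k];
      f[3 * fa + k] += dEdd * da[k];
      f[3 * lb + k] -= dEdd * db[k];
      f[3 * fb + k] += dEdd * db[k];
    }
  }

  return e;
}

// ------------------------------------------------------------ exports ----

static List energy_list(const EComp& e, const std::vector<double>& f, int N) {
  NumericMatrix fm(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = f[3 * i + k];
  return List::create(_["energy"] = e.total(), _["forces"] = fm,
                      _["e_bond"] = e.bond, _["e_angle"] = e.angle,
                      _["e_rep"] = e.rep, _["e_sticky"] = e.sticky);
}

static std::vector<double> mat_to_vec(const NumericMatrix& pos) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  return x;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box, List topo,
                       List params, bool all_pairs = false) {
  Topo t = read_topo(topo);
  Par p = read_par(params);
  std::vector<double> x = mat_to_vec(pos);
  double bx[3] = {box[0], box[1], box[2]};
  NList nl;
  if (all_pairs) {
    // exhaustive candidate lists (no distance filtering beyond cutoffs)
    nl.built = true;
    for (int i = 0; i < t.N; ++i)
      for (int j = i + 1; j < t.N; ++j) {
        if (t.chain[i] == t.chain[j] && excluded(t, i, j)) continue;
        nl.rep_pairs.push_back({i, j, (int8_t)(fat_pair(t, i, j) ? 1 : 0)});
        Pair pr;
        pr.i = i;
        pr.j = j;
        classify_pair(t, i, j, pr.code, pr.strength);
        if (pr.code > 0) nl.sticky_pairs.push_back(pr);
      }
  } else {
    build_nlist(x, bx, t, p, nl);
  }
  std::vector<double> f;
  EComp e = compute_forces(x, bx, t, p, nl, f);
  return energy_list(e, f, t.N);
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, NumericVector box, List topo, List params,
                  int max_steps, double force_tol, double max_disp) {
  Topo t = read_topo(topo);
  Par p = read_par(params);
  std::vector<double> x = mat_to_vec(pos);
  double bx[3] = {box[0], box[1], box[2]};
  NList nl;
  build_nlist(x, bx, t, p, nl);
  std::vector<double> f;
  EComp e = compute_forces(x, bx, t, p, nl, f);
  double energy = e.total();
  double alpha = 1e-5;
  int step = 0;
  double maxf = 0;
  std::vector<double> xtrial(x.size());
  for (step = 0; step < max_steps; ++step) {
    maxf = 0;
    for (size_t i = 0; i < f.size(); i += 3) {
      double fm = std::sqrt(f[i] * f[i] + f[i + 1] * f[i + 1] +
                            f[i + 2] * f[i + 2]);
      if (fm > maxf) maxf = fm;
    }
    if (maxf < force_tol) break;
    double scale = alpha;
    if (scale * maxf > max_disp) scale = max_disp / maxf;
    for (size_t i = 0; i < x.size(); ++i) xtrial[i] = x[i] + scale * f[i];
    if (nlist_stale(xtrial, nl, p)) build_nlist(xtrial, bx, t, p, nl);
    std::vector<double> ftrial;
    EComp et = compute_forces(xtrial, bx, t, p, nl, ftrial);
    if (et.total() <= energy) {
      x.swap(xtrial);
      f.swap(ftrial);
      energy = et.total();
      e = et;
      alpha *= 1.2;
    } else {
      alpha *= 0.5;
      if (alpha < 1e-12) break;
    }
  }
  NumericMatrix out(t.N, 3);
  for (int i = 0; i < t.N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return List::create(_["pos"] = out, _["energy"] = energy,
                      _["max_force"] = maxf, _["n_steps"] = step,
                      _["converged"] = maxf < force_tol);
}

// [[Rcpp::export]]
List cpp_langevin(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                  List topo, List params, double dt, double gamma, double kT,
                  int n_steps, int save_interval, double seed,
                  int com_interval, double t0) {
  Topo t = read_topo(topo);
  Par p = read_par(params);
  std::vector<double> x = mat_to_vec(pos);
  std::vector<double> v = mat_to_vec(vel);
  double bx[3] = {box[0], box[1], box[2]};
  Rng rng((uint64_t)seed);
  double m = p.mass;
  double c1 = gamma > 0 ? std::exp(-gamma * dt) : 1.0;
  double c2 = gamma > 0 ? std::sqrt(kT * (1.0 - c1 * c1) / m) : 0.0;

  NList nl;
  build_nlist(x, bx, t, p, nl);
  std::vector<double> f;
  EComp e = compute_forces(x, bx, t, p, nl, f);

  int n_saved = n_steps / save_interval;
  NumericVector frames((R_xlen_t)n_saved * t.N * 3);
  NumericVector times(n_saved), pe(n_saved), ke(n_saved);
  int fi = 0;
  bool blowup = false;
  int blowup_step = -1;
  double half = 0.5 * dt;
  double maxmove = 0.45 * std::min(bx[0], std::min(bx[1], bx[2]));

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (size_t i = 0; i < v.size(); ++i) v[i] += half * f[i] / m;
    // A
    for (size_t i = 0; i < x.size(); ++i) x[i] += half * v[i];
    // O
    if (gamma > 0)
      for (size_t i = 0; i < v.size(); ++i)
        v[i] = c1 * v[i] + c2 * rng.gauss();
    // A
    double maxstep2 = 0;
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = half * v[i], dy = half * v[i + 1], dz = half * v[i + 2];
      x[i] += dx;
      x[i + 1] += dy;
      x[i + 2] += dz;
      double s2 = dx * dx + dy * dy + dz * dz;
      if (s2 > maxstep2) maxstep2 = s2;
    }
    if (maxstep2 > maxmove * maxmove) {
      blowup = true;
      blowup_step = step;
      break;
    }
    if (nlist_stale(x, nl, p)) build_nlist(x, bx, t, p, nl);
    e = compute_forces(x, bx, t, p, nl, f);
    // B
    for (size_t i = 0; i < v.size(); ++i) v[i] += half * f[i] / m;

    if (com_interval > 0 && step % com_interval == 0) {
      double vc[3] = {0, 0, 0};
      for (size_t i = 0; i < v.size(); i += 3)
        for (int k = 0; k < 3; ++k) vc[k] += v[i + k];
      for (int k = 0; k < 3; ++k) vc[k] /= t.N;
      for (size_t i = 0; i < v.size(); i += 3)
        for (int k = 0; k < 3; ++k) v[i + k] -= vc[k];
    }

    if (step % save_interval == 0 && fi < n_saved) {
      double kin = 0;
      for (size_t i = 0; i < v.size(); ++i) kin += v[i] * v[i];
      kin *= 0.5 * m;
      times[fi] = t0 + step * dt;
      pe[fi] = e.total();
      ke[fi] = kin;
      for (int i = 0; i < t.N; ++i)
        for (int k = 0; k < 3; ++k)
          frames[(R_xlen_t)fi * t.N * 3 + (R_xlen_t)i * 3 + k] = x[3 * i + k];
      ++fi;
    }
  }

  NumericMatrix xp(t.N, 3), vp(t.N, 3);
  for (int i = 0; i < t.N; ++i)
    for (int k = 0; k < 3; ++k) {
      xp(i, k) = x[3 * i + k];
      vp(i, k) = v[3 * i + k];
    }
  return List::create(_["frames"] = frames, _["times"] = times, _["pe"] = pe,
                      _["ke"] = ke, _["n_saved"] = fi, _["pos"] = xp,
                      _["vel"] = vp, _["blowup"] = blowup,
                      _["blowup_step"] = blowup_step);
}

// Per-frame complementary contact counts between coil segments.
// Returns rows (frame, seg_a, seg_b, n_beads_a_touching_b) for ordered pairs
// seg_a != seg_b with at least one bead of seg_a within `cutoff` of a
// registry-complementary bead of seg_b.
// [[Rcpp::export]]
IntegerMatrix cpp_traj_contacts(NumericVector frames, int n_frames, int n_beads,
                                NumericVector box, List topo, double cutoff) {
  Topo t = read_topo(topo);
  double bx[3] = {box[0], box[1], box[2]};
  double c2 = cutoff * cutoff;

  // enumerate static complementary bead pairs (i<j)
  std::vector<std::pair<int, int>> cand;
  for (int i = 0; i < t.N; ++i) {
    if (t.type[i] <= 0) continue;
    for (int j = i + 1; j < t.N; ++j) {
      if (t.type[j] <= 0 || t.seg[i] == t.seg[j]) continue;
      int code = t.pair_code[(t.type[i] - 1) * t.ntype + (t.type[j] - 1)];
      if (code > 0 && complementary(t, i, j, code) &&
          t.pair_strength[(t.type[i] - 1) * t.ntype + (t.type[j] - 1)] > 0)
        cand.push_back({i, j});
    }
  }

  std::vector<int> rows;
  std::map<std::pair<int, int>, std::vector<char>> touched; // seg pair -> beads
  for (int fr = 0; fr < n_frames; ++fr) {
    touched.clear();
    const double* xf = &frames[(R_xlen_t)fr * n_beads * 3];
    for (auto& pr : cand) {
      int i = pr.first, j = pr.second;
      double d[3] = {xf[3 * i] - xf[3 * j], xf[3 * i + 1] - xf[3 * j + 1],
                     xf[3 * i + 2] - xf[3 * j + 2]};
      min_image(d, bx);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < c2) {
        int sa = t.seg[i], sb = t.seg[j];
        auto ka = std::make_pair(sa, sb);
        auto kb = std::make_pair(sb, sa);
        auto& va = touched[ka];
        if (va.empty()) va.assign(t.clen[i] + 1, 0);
        va[t.reg[i]] = 1;
        auto& vb = touched[kb];
        if (vb.empty()) vb.assign(t.clen[j] + 1, 0);
        vb[t.reg[j]] = 1;
      }
    }
    for (auto& kv : touched) {
      int n = 0;
      for (char c : kv.second) n += c;
      rows.push_back(fr + 1);
      rows.push_back(kv.first.first);
      rows.push_back(kv.first.second);
      rows.push_back(n);
    }
  }
  int nr = rows.size() / 4;
  IntegerMatrix out(nr, 4);
  for (int r = 0; r < nr; ++r)
    for (int k = 0; k < 4; ++k) out(r, k) = rows[4 * r + k];
  colnames(out) = CharacterVector::create("frame", "seg_a", "seg_b",
                                          "n_contact");
  return out;
}

// Minimum nonbonded pair distance (minimum image); small-system diagnostic.
// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix pos, NumericVector box, List topo) {
  Topo t = read_topo(topo);
  std::vector<double> x = mat_to_vec(pos);
  double bx[3] = {box[0], box[1], box[2]};
  double best = R_PosInf;
  for (int i = 0; i < t.N; ++i)
    for (int j = i + 1; j < t.N; ++j) {
      if (t.chain[i] == t.chain[j] && excluded(t, i, j)) continue;
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      min_image(d, bx);
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (r < best) best = r;
    }
  return best;
}
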