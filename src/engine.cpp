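// Photon-only Monte Carlo transport with track-length and analogue kerma
// tallies.  Geometry: voxel grid (Woodcock delta tracking), homogeneous
// sphere, or vacuum world, each with an optional embedded analytic source
// capsule (nested finite cylinders) that overrides the world medium.
// No electron transport: photoelectric absorbs locally, Compton transfers
// E - E' locally, Rayleigh is elastic.  1 keV default cut-off.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double MEC2 = 510.99895;     // keV
static const double HCKEVA = 12.398420;   // keV * Angstrom
static const double INF = std::numeric_limits<double>::infinity();
static const double EPSB = 1e-7;          // boundary nudge, cm

// ---------------------------------------------------------------- RNG ----
// PCG32; one stream per history (stream selector = history index), so the
// result is independent of any batch decomposition.
struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u; inc = (initseq << 1u) | 1u;
    next(); state += initstate; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31));
  }
  double u() { return (next() + 0.5) * 2.3283064365386963e-10; }
};

static uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// ------------------------------------------------------------ XS data ----
enum Channel { CH_PE = 0, CH_CO = 1, CH_RA = 2, CH_TOT = 3, CH_MUEN = 4 };

struct XsTab {
  std::vector<double> logE;
  std::vector<double> logv[5];
  double rho;                      // nominal density g/cm3
  double emin, emax;

  double lookup(int ch, double E) const {
    double le = std::log(E);
    const std::vector<double>& y = logv[ch];
    size_t n = logE.size();
    if (le <= logE[0]) return std::exp(y[0]);
    if (le >= logE[n - 1]) return std::exp(y[n - 1]);
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) { size_t m = (lo + hi) / 2; (logE[m] <= le ? lo : hi) = m; }
    double f = (le - logE[lo]) / (logE[hi] - logE[lo]);
    return std::exp(y[lo] + f * (y[hi] - y[lo]));
  }
};

// Rayleigh sampling table: cumulative of F^2 over x^2
struct FfTab {
  std::vector<double> x2, cum, f2;
  double x2max_all;
};

struct Materials {
  std::vector<XsTab> xs;
  std::vector<FfTab> ff;
  // caches refreshed when the photon energy changes
  double cachedE = -1.0;
  std::vector<double> mu_tot, muen;           // cm2/g at cachedE
  void refresh(double E) {
    if (E == cachedE) return;
    for (size_t m = 0; m < xs.size(); ++m) {
      mu_tot[m] = xs[m].lookup(CH_TOT, E);
      muen[m] = xs[m].lookup(CH_MUEN, E);
    }
    cachedE = E;
  }
};

// ---------------------------------------------------------- geometry -----
struct V3 { double x, y, z; };
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Rot { double m[9]; // row-major local->world
  V3 toWorld(V3 v) const {
    return {m[0] * v.x + m[1] * v.y + m[2] * v.z,
            m[3] * v.x + m[4] * v.y + m[5] * v.z,
            m[6] * v.x + m[7] * v.y + m[8] * v.z};
  }
  V3 toLocal(V3 v) const {
    return {m[0] * v.x + m[3] * v.y + m[6] * v.z,
            m[1] * v.x + m[4] * v.y + m[7] * v.z,
            m[2] * v.x + m[5] * v.y + m[8] * v.z};
  }
};

// finite cylinder centred on local z in [zlo, zhi], radius r
static bool inside_cyl(V3 p, double r, double zlo, double zhi) {
  return p.z > zlo && p.z < zhi && (p.x * p.x + p.y * p.y) < r * r;
}

// parametric interval [t0,t1] of the ray inside the cylinder; empty -> t0>t1
static void cyl_interval(V3 p, V3 d, double r, double zlo, double zhi,
                         double& t0, double& t1) {
  double ta = -INF, tb = INF;
  // z slab
  if (std::fabs(d.z) < 1e-14) {
    if (p.z <= zlo || p.z >= zhi) { t0 = 1; t1 = 0; return; }
  } else {
    double u0 = (zlo - p.z) / d.z, u1 = (zhi - p.z) / d.z;
    if (u0 > u1) std::swap(u0, u1);
    ta = std::max(ta, u0); tb = std::min(tb, u1);
  }
  // infinite cylinder
  double a = d.x * d.x + d.y * d.y;
  double b = p.x * d.x + p.y * d.y;
  double c = p.x * p.x + p.y * p.y - r * r;
  if (a < 1e-14) {
    if (c >= 0) { t0 = 1; t1 = 0; return; }
  } else {
    double disc = b * b - a * c;
    if (disc <= 0) { t0 = 1; t1 = 0; return; }
    double sq = std::sqrt(disc);
    double u0 = (-b - sq) / a, u1 = (-b + sq) / a;
    ta = std::max(ta, u0); tb = std::min(tb, u1);
  }
  t0 = ta; t1 = tb;
}

static double cyl_exit(V3 p, V3 d, double r, double zlo, double zhi) {
  double t0, t1; cyl_interval(p, d, r, zlo, zhi, t0, t1);
  return (t1 > 0) ? t1 : 0.0;
}
static double cyl_entry(V3 p, V3 d, double r, double zlo, double zhi) {
  double t0, t1; cyl_interval(p, d, r, zlo, zhi, t0, t1);
  if (t1 <= t0 || t1 <= EPSB) return INF;
  return std::max(t0, 0.0) + (t0 > EPSB ? 0.0 : 0.0);
}

struct Capsule {
  bool present = false;
  V3 origin; Rot rot;
  double core_r, core_hl; int core_mat;
  double cap_r, cap_hl; int cap_mat;
  double cable_r, cable_len; int cable_mat;  // z in [-cap_hl-cable_len, -cap_hl]
  // region codes: -1 outside, 0 core, 1 shell, 2 cable
  int region(V3 pl) const {
    if (inside_cyl(pl, core_r, -core_hl, core_hl)) return 0;
    if (inside_cyl(pl, cap_r, -cap_hl, cap_hl)) return 1;
    if (cable_len > 0 &&
        inside_cyl(pl, cable_r, -cap_hl - cable_len, -cap_hl)) return 2;
    return -1;
  }
  int mat(int reg) const {
    return reg == 0 ? core_mat : (reg == 1 ? cap_mat : cable_mat);
  }
  double boundary(V3 pl, V3 dl, int reg) const {
    if (reg == 0) return cyl_exit(pl, dl, core_r, -core_hl, core_hl);
    if (reg == 2) return cyl_exit(pl, dl, cable_r, -cap_hl - cable_len, -cap_hl);
    double t = cyl_exit(pl, dl, cap_r, -cap_hl, cap_hl);
    double tc = cyl_entry(pl, dl, core_r, -core_hl, core_hl);
    return std::min(t, tc);
  }
  double entry(V3 pl, V3 dl) const {   // from outside
    double t = cyl_entry(pl, dl, cap_r, -cap_hl, cap_hl);
    if (cable_len > 0)
      t = std::min(t, cyl_entry(pl, dl, cable_r, -cap_hl - cable_len, -cap_hl));
    return t;
  }
};

// ------------------------------------------------------------- grids -----
struct ScoreGrid {
  int nx = 0, ny = 0, nz = 0;
  double sx, sy, sz, ox, oy, oz, vol;
  std::vector<int> mat;            // per voxel material (0-based)
  std::vector<double> rho;         // per voxel density (analogue scorer)
  bool tlke = false, analog = false;
  std::vector<double> t_sum, t_sumsq, t_buf;
  std::vector<double> a_sum, a_sumsq, a_buf;
  std::vector<int> t_touch, a_touch;

  size_t nvox() const { return (size_t)nx * ny * nz; }
  void flush() {
    for (int v : t_touch) {
      t_sum[v] += t_buf[v]; t_sumsq[v] += t_buf[v] * t_buf[v]; t_buf[v] = 0;
    }
    t_touch.clear();
    for (int v : a_touch) {
      a_sum[v] += a_buf[v]; a_sumsq[v] += a_buf[v] * a_buf[v]; a_buf[v] = 0;
    }
    a_touch.clear();
  }
  void add_tlke(int v, double val) {
    if (val == 0) return;
    if (t_buf[v] == 0) t_touch.push_back(v);
    t_buf[v] += val;
  }
  void add_analog(int v, double val) {
    if (val == 0) return;
    if (a_buf[v] == 0) a_touch.push_back(v);
    a_buf[v] += val;
  }
  int voxel_at(V3 p) const {
    int i = (int)std::floor((p.x - ox) / sx);
    int j = (int)std::floor((p.y - oy) / sy);
    int k = (int)std::floor((p.z - oz) / sz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return i + nx * (j + (size_t)ny * k);
  }
};

struct RingCell {
  V3 origin; Rot rot;
  double r_in, r_out, half_h; int mat;
  double vol;
  double sum = 0, sumsq = 0, buf = 0;
  bool touched = false;
  // chord length of segment p -> p+L*d inside the annulus (local frame)
  double chord(V3 pw, V3 dw, double L) const {
    V3 pl = rot.toLocal(pw - origin);
    V3 dl = rot.toLocal(dw);
    double o0, o1, i0, i1;
    cyl_interval(pl, dl, r_out, -half_h, half_h, o0, o1);
    if (o1 <= o0) return 0.0;
    o0 = std::max(o0, 0.0); o1 = std::min(o1, L);
    if (o1 <= o0) return 0.0;
    cyl_interval(pl, dl, r_in, -half_h, half_h, i0, i1);
    double len = o1 - o0;
    if (i1 > i0) {                      // subtract the inner-cylinder overlap
      double s0 = std::max(i0, o0), s1 = std::min(i1, o1);
      if (s1 > s0) len -= (s1 - s0);
    }
    return len;
  }
};

// ------------------------------------------------------------- scene -----
struct Phantom {
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;
  const int* mat;        // 0-based material ids
  const double* rho;
  bool inside(V3 p) const {
    return p.x > ox && p.y > oy && p.z > oz &&
           p.x < ox + nx * sx && p.y < oy + ny * sy && p.z < oz + nz * sz;
  }
  // [t0,t1] of ray within bounding box
  void bbox_interval(V3 p, V3 d, double& t0, double& t1) const {
    t0 = -INF; t1 = INF;
    double lo[3] = {ox, oy, oz};
    double hi[3] = {ox + nx * sx, oy + ny * sy, oz + nz * sz};
    double pp[3] = {p.x, p.y, p.z}, dd[3] = {d.x, d.y, d.z};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dd[a]) < 1e-14) {
        if (pp[a] <= lo[a] || pp[a] >= hi[a]) { t0 = 1; t1 = 0; return; }
      } else {
        double u0 = (lo[a] - pp[a]) / dd[a], u1 = (hi[a] - pp[a]) / dd[a];
        if (u0 > u1) std::swap(u0, u1);
        t0 = std::max(t0, u0); t1 = std::min(t1, u1);
      }
    }
  }
  int voxel(V3 p, int& i, int& j, int& k) const {
    i = (int)std::floor((p.x - ox) / sx);
    j = (int)std::floor((p.y - oy) / sy);
    k = (int)std::floor((p.z - oz) / sz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return i + nx * (j + (size_t)ny * k);
  }
};

enum WorldType { W_VACUUM = 0, W_SPHERE = 1, W_VOXEL = 2 };

struct Tallies {
  std::vector<ScoreGrid*> grids;
  std::vector<RingCell*> rings;
  Materials* mats;
  bool kerma_caveat = false;

  void segment(V3 p, V3 d, double L, double E, double wt) {
    if (L <= 0) return;
    for (RingCell* rc : rings) {
      double l = rc->chord(p, d, L);
      if (l > 0) {
        double muen = mats->xs[rc->mat].lookup(CH_MUEN, E);
        double v = wt * l * E * 1000.0 * muen / rc->vol;   // eV/g
        if (rc->buf == 0) rc->touched = true;
        rc->buf += v;
      }
    }
    for (ScoreGrid* g : grids) {
      if (!g->tlke) continue;
      siddon(*g, p, d, L, E, wt);
    }
  }

  void siddon(ScoreGrid& g, V3 p, V3 d, double L, double E, double wt) {
    // clip to grid bbox
    double t0 = 0.0, t1 = L;
    double lo[3] = {g.ox, g.oy, g.oz};
    double hi[3] = {g.ox + g.nx * g.sx, g.oy + g.ny * g.sy, g.oz + g.nz * g.sz};
    double pp[3] = {p.x, p.y, p.z}, dd[3] = {d.x, d.y, d.z};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(dd[a]) < 1e-14) {
        if (pp[a] <= lo[a] || pp[a] >= hi[a]) return;
      } else {
        double u0 = (lo[a] - pp[a]) / dd[a], u1 = (hi[a] - pp[a]) / dd[a];
        if (u0 > u1) std::swap(u0, u1);
        t0 = std::max(t0, u0); t1 = std::min(t1, u1);
      }
    }
    if (t1 <= t0) return;
    double t = t0 + 1e-12 * (t1 - t0);
    V3 q = p + t * d;
    int i, j, k;
    i = (int)std::floor((q.x - g.ox) / g.sx);
    j = (int)std::floor((q.y - g.oy) / g.sy);
    k = (int)std::floor((q.z - g.oz) / g.sz);
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    if (i >= g.nx) i = g.nx - 1; if (j >= g.ny) j = g.ny - 1; if (k >= g.nz) k = g.nz - 1;
    int si = dd[0] > 0 ? 1 : -1, sj = dd[1] > 0 ? 1 : -1, sk = dd[2] > 0 ? 1 : -1;
    double tx = (std::fabs(dd[0]) < 1e-14) ? INF :
      ((g.ox + (i + (si > 0 ? 1 : 0)) * g.sx) - pp[0]) / dd[0];
    double ty = (std::fabs(dd[1]) < 1e-14) ? INF :
      ((g.oy + (j + (sj > 0 ? 1 : 0)) * g.sy) - pp[1]) / dd[1];
    double tz = (std::fabs(dd[2]) < 1e-14) ? INF :
      ((g.oz + (k + (sk > 0 ? 1 : 0)) * g.sz) - pp[2]) / dd[2];
    double dtx = std::fabs(g.sx / dd[0]), dty = std::fabs(g.sy / dd[1]),
           dtz = std::fabs(g.sz / dd[2]);
    double tc = t0;
    double e1000 = E * 1000.0 * wt / g.vol;
    while (tc < t1 - 1e-13) {
      double tn = std::min(std::min(tx, ty), std::min(tz, t1));
      double len = tn - tc;
      if (len > 0) {
        int v = i + g.nx * (j + (size_t)g.ny * k);
        double muen = mats->muen[g.mat[v]];
        g.add_tlke(v, e1000 * len * muen);
      }
      if (tn >= t1 - 1e-13) break;
      if (tx <= ty && tx <= tz) { i += si; tx += dtx; }
      else if (ty <= tz) { j += sj; ty += dty; }
      else { k += sk; tz += dtz; }
      if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz) break;
      tc = tn;
    }
  }

  void deposit(V3 p, double Edep, double wt) {
    for (ScoreGrid* g : grids) {
      if (!g->analog) continue;
      int v = g->voxel_at(p);
      if (v >= 0)
        g->add_analog(v, wt * Edep * 1000.0 / (g->rho[v] * g->vol));
    }
  }

  void flush() {
    for (ScoreGrid* g : grids) g->flush();
    for (RingCell* rc : rings) {
      if (rc->touched) {
        rc->sum += rc->buf; rc->sumsq += rc->buf * rc->buf;
        rc->buf = 0; rc->touched = false;
      }
    }
  }
};

// --------------------------------------------------------- sampling ------
static double sample_line(const std::vector<double>& cumI,
                          const std::vector<double>& EL, Pcg32& rng) {
  double u = rng.u() * cumI.back();
  size_t lo = 0, hi = cumI.size() - 1;
  while (hi > lo) { size_t m = (lo + hi) / 2; if (cumI[m] < u) lo = m + 1; else hi = m; }
  return EL[lo];
}

static void iso_dir(Pcg32& rng, V3& d) {
  double c = 2.0 * rng.u() - 1.0, s = std::sqrt(std::max(0.0, 1 - c * c));
  double ph = 2.0 * M_PI * rng.u();
  d = {s * std::cos(ph), s * std::sin(ph), c};
}

static void rotate_dir(V3& d, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d.x, uy = d.y, uz = d.z;
  double norm = std::sqrt(ux * ux + uy * uy);
  V3 nd;
  if (norm > 1e-12) {
    nd.x = ux * cost + sint * (ux * uz * cp - uy * sp) / norm;
    nd.y = uy * cost + sint * (uy * uz * cp + ux * sp) / norm;
    nd.z = uz * cost - norm * sint * cp;
  } else {
    nd.x = sint * cp; nd.y = sint * sp; nd.z = (uz > 0 ? cost : -cost);
  }
  double n = std::sqrt(dot(nd, nd));
  d = (1.0 / n) * nd;
}

// Kahn's rejection method for the Klein-Nishina distribution
static void sample_compton(double E, Pcg32& rng, double& Ep, double& cost) {
  double a = E / MEC2;
  double x;
  for (;;) {
    double u1 = rng.u(), u2 = rng.u(), u3 = rng.u();
    if (u1 * (2 * a + 9) <= 2 * a + 1) {
      x = 1 + 2 * a * u2;
      if (u3 <= 4 * (1 / x - 1 / (x * x))) break;
    } else {
      x = (1 + 2 * a) / (1 + 2 * a * u2);
      double c = 1 - (x - 1) / a;
      if (u3 <= 0.5 * (c * c + 1 / x)) break;
    }
  }
  cost = 1 - (x - 1) / a;
  Ep = E / x;
}

// form-factor-weighted Rayleigh angle
static double sample_rayleigh(const FfTab& ff, double E, Pcg32& rng) {
  double k = E / HCKEVA;                      // 1/Angstrom
  double x2max = k * k;                       // at theta = pi, x = k
  // cumulative at x2max
  size_t n = ff.x2.size();
  // the tabulated F^2 is piecewise linear in x^2 and the cumulative is its
  // exact (trapezoid) integral; both evaluation and inversion below keep
  // that representation exactly
  double cmax;
  if (x2max >= ff.x2.back()) cmax = ff.cum.back();
  else {
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) { size_t m = (lo + hi) / 2; (ff.x2[m] <= x2max ? lo : hi) = m; }
    double dx = ff.x2[hi] - ff.x2[lo];
    double t = x2max - ff.x2[lo];
    double slope = (ff.f2[hi] - ff.f2[lo]) / dx;
    cmax = ff.cum[lo] + ff.f2[lo] * t + 0.5 * slope * t * t;
  }
  for (int it = 0; it < 10000; ++it) {
    double c = rng.u() * cmax;
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) { size_t m = (lo + hi) / 2; (ff.cum[m] <= c ? lo : hi) = m; }
    double dx = ff.x2[hi] - ff.x2[lo];
    double slope = (ff.f2[hi] - ff.f2[lo]) / dx;
    double dc = c - ff.cum[lo];
    double f1 = ff.f2[lo], t;
    if (std::fabs(slope) * dx < 1e-12 * std::max(f1, 1e-300)) {
      t = dc / std::max(f1, 1e-300);
    } else {
      double disc = f1 * f1 + 2.0 * slope * dc;
      t = (-f1 + std::sqrt(std::max(disc, 0.0))) / slope;
    }
    if (t < 0) t = 0; if (t > dx) t = dx;
    double x2 = ff.x2[lo] + t;
    double cost = 1.0 - 2.0 * x2 / x2max;
    if (rng.u() <= 0.5 * (1 + cost * cost)) return cost;
  }
  return 1.0;
}

// ------------------------------------------------------------ engine -----
struct Particle { V3 p, d; double E, wt; };

struct Engine {
  Materials mats;
  Capsule caps;
  Tallies tal;
  WorldType wtype;
  double sphere_R = 0; int sphere_mat = 0;
  Phantom ph;
  std::vector<double> maj_cache; double maj_E = -1; double majorant_margin = 1.01;
  double world_R = 150.0;            // scoring horizon in vacuum, cm
  double cutoff = 1.0;
  bool primaries_only = false;
  bool collect_psf = false;
  // per-run accumulators
  double E_emitted = 0, E_escaped = 0, E_deposited = 0, max_resid = 0;
  double n_uncollided = 0;           // histories escaping with no interaction
  std::vector<double> psf;           // collected records (E,x,y,z,u,v,w,wt)
  size_t psf_max = 0;

  double majorant(double E) {
    if (E != maj_E) {
      double m = 0;
      for (size_t i = 0; i < maj_cache.size(); ++i) {
        double v = maj_cache[i] * mats.xs[i].lookup(CH_TOT, E);
        if (v > m) m = v;
      }
      maj_E = E; maj_val = m * majorant_margin;
    }
    return maj_val;
  }
  double maj_val = 0;

  // track one particle (and its Compton descendants: the chain is sequential
  // since each interaction yields at most one surviving photon)
  void track(Particle pt, Pcg32& rng, bool& any_interaction) {
    while (true) {
      if (pt.E < cutoff) { tal.deposit(pt.p, pt.E, pt.wt); E_deposited += pt.wt * pt.E; return; }
      mats.refresh(pt.E);
      V3 pl, dl; int reg = -1;
      if (caps.present) {
        pl = caps.rot.toLocal(pt.p - caps.origin);
        dl = caps.rot.toLocal(pt.d);
        reg = caps.region(pl);
      }
      if (reg >= 0) {
        int m = caps.mat(reg);
        double mu = mats.xs[m].rho * mats.mu_tot[m];
        double tb = caps.boundary(pl, dl, reg);
        double s = -std::log(rng.u()) / mu;
        if (s < tb) {
          tal.segment(pt.p, pt.d, s, pt.E, pt.wt);
          pt.p = pt.p + s * pt.d;
          any_interaction = true;
          if (!interact(pt, m, rng)) return;
        } else {
          tal.segment(pt.p, pt.d, tb + EPSB, pt.E, pt.wt);
          pt.p = pt.p + (tb + EPSB) * pt.d;
          if (caps.present && collect_psf &&
              caps.region(caps.rot.toLocal(pt.p - caps.origin)) < 0) {
            // leaving the capsule: optionally record a phase-space row
            if (psf.size() / 8 < psf_max) {
              V3 rp = caps.rot.toLocal(pt.p - caps.origin);
              V3 rd = caps.rot.toLocal(pt.d);
              psf.push_back(pt.E); psf.push_back(rp.x); psf.push_back(rp.y);
              psf.push_back(rp.z); psf.push_back(rd.x); psf.push_back(rd.y);
              psf.push_back(rd.z); psf.push_back(pt.wt);
            }
          }
        }
        continue;
      }
      // in the world medium
      if (wtype == W_VACUUM) {
        double tb = caps.present ? caps.entry(
          caps.rot.toLocal(pt.p - caps.origin), caps.rot.toLocal(pt.d)) : INF;
        // scoring horizon: segment clipped to |p| < world_R sphere
        double thor = horizon(pt.p, pt.d);
        double L = std::min(tb, thor);
        if (L > 0) tal.segment(pt.p, pt.d, L, pt.E, pt.wt);
        if (tb < thor) { pt.p = pt.p + (tb + EPSB) * pt.d; continue; }
        E_escaped += pt.wt * pt.E; return;
      } else if (wtype == W_SPHERE) {
        double r2 = dot(pt.p, pt.p);
        if (r2 >= sphere_R * sphere_R) { E_escaped += pt.wt * pt.E; return; }
        double mu = mats.xs[sphere_mat].rho * mats.mu_tot[sphere_mat];
        double tb = sphere_exit(pt.p, pt.d);
        if (caps.present) {
          double tc = caps.entry(caps.rot.toLocal(pt.p - caps.origin),
                                 caps.rot.toLocal(pt.d));
          if (tc < tb) {
            double s = -std::log(rng.u()) / mu;
            if (s < tc) {
              tal.segment(pt.p, pt.d, s, pt.E, pt.wt);
              pt.p = pt.p + s * pt.d; any_interaction = true;
              if (!interact(pt, sphere_mat, rng)) return;
              continue;
            }
            tal.segment(pt.p, pt.d, tc + EPSB, pt.E, pt.wt);
            pt.p = pt.p + (tc + EPSB) * pt.d;
            continue;
          }
        }
        double s = -std::log(rng.u()) / mu;
        if (s < tb) {
          tal.segment(pt.p, pt.d, s, pt.E, pt.wt);
          pt.p = pt.p + s * pt.d; any_interaction = true;
          if (!interact(pt, sphere_mat, rng)) return;
        } else {
          tal.segment(pt.p, pt.d, tb + EPSB, pt.E, pt.wt);
          E_escaped += pt.wt * pt.E; return;
        }
        continue;
      }
      // voxel world, Woodcock tracking
      {
        double t0, t1;
        ph.bbox_interval(pt.p, pt.d, t0, t1);
        if (t1 <= 0 || t1 <= t0) { E_escaped += pt.wt * pt.E; return; }
        if (t0 > 0) {  // outside the box: advance to it (vacuum outside)
          tal.segment(pt.p, pt.d, t0 + EPSB, pt.E, pt.wt);
          pt.p = pt.p + (t0 + EPSB) * pt.d;
          continue;
        }
        double smaj = majorant(pt.E);
        double tcap = caps.present ? caps.entry(
          caps.rot.toLocal(pt.p - caps.origin), caps.rot.toLocal(pt.d)) : INF;
        double s = -std::log(rng.u()) / smaj;
        double L = std::min(std::min(s, tcap), t1);
        tal.segment(pt.p, pt.d, std::min(L + EPSB, t1), pt.E, pt.wt);
        pt.p = pt.p + (L + EPSB) * pt.d;
        if (s <= tcap && s <= t1) {
          int i, j, k;
          int v = ph.voxel(pt.p, i, j, k);
          if (v < 0) continue;
          int m = ph.mat[v];
          double mu_real = ph.rho[v] * mats.mu_tot[m];
          if (mu_real > smaj * (1 + 1e-9))
            stop("woodcock majorant smaller than local attenuation");
          if (rng.u() * smaj < mu_real) {
            any_interaction = true;
            if (!interact(pt, m, rng)) return;
          }
        } else if (tcap < t1) {
          continue;  // entered the capsule
        } else {
          E_escaped += pt.wt * pt.E; return;
        }
      }
    }
  }

  double horizon(V3 p, V3 d) const {
    // distance to |p + t d| = world_R (assumes |p| < world_R)
    double b = dot(p, d), c = dot(p, p) - world_R * world_R;
    double disc = b * b - c;
    if (disc <= 0) return 0;
    return -b + std::sqrt(disc);
  }
  double sphere_exit(V3 p, V3 d) const {
    double b = dot(p, d), c = dot(p, p) - sphere_R * sphere_R;
    double disc = b * b - c;
    if (disc <= 0) return 0;
    return -b + std::sqrt(disc);
  }

  // returns false if the photon died
  bool interact(Particle& pt, int m, Pcg32& rng) {
    if (primaries_only) {           // analogue bookkeeping then stop
      tal.deposit(pt.p, pt.E, pt.wt);
      E_deposited += pt.wt * pt.E;
      return false;
    }
    const XsTab& xs = mats.xs[m];
    double pe = xs.lookup(CH_PE, pt.E), co = xs.lookup(CH_CO, pt.E),
           ra = xs.lookup(CH_RA, pt.E);
    double u = rng.u() * (pe + co + ra);
    if (u < pe) {                   // photoelectric: local absorption
      tal.deposit(pt.p, pt.E, pt.wt);
      E_deposited += pt.wt * pt.E;
      return false;
    } else if (u < pe + co) {       // Compton
      double Ep, cost;
      sample_compton(pt.E, rng, Ep, cost);
      double Edep = pt.E - Ep;
      tal.deposit(pt.p, Edep, pt.wt);
      E_deposited += pt.wt * Edep;
      rotate_dir(pt.d, cost, 2 * M_PI * rng.u());
      if (Ep < cutoff) {
        tal.deposit(pt.p, Ep, pt.wt);
        E_deposited += pt.wt * Ep;
        return false;
      }
      pt.E = Ep;
      return true;
    } else {                        // Rayleigh: elastic
      double cost = sample_rayleigh(mats.ff[m], pt.E, rng);
      rotate_dir(pt.d, cost, 2 * M_PI * rng.u());
      return true;
    }
  }
};

// ------------------------------------------------------- R interface -----
static Rot rot_from(NumericMatrix R) {
  Rot r;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) r.m[3 * i + j] = R(i, j);
  return r;
}

static void load_materials(List mlist, List fflist, Materials& M) {
  int n = mlist.size();
  M.xs.resize(n); M.ff.resize(n);
  M.mu_tot.assign(n, 0); M.muen.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    List t = mlist[i];
    NumericVector E = t["energy"], pe = t["pe"], co = t["compton"],
      ra = t["rayleigh"], tot = t["total"], muen = t["muen"];
    XsTab& x = M.xs[i];
    x.rho = as<double>(t["density"]);
    size_t m = E.size();
    x.logE.resize(m);
    for (int ch = 0; ch < 5; ++ch) x.logv[ch].resize(m);
    for (size_t j = 0; j < m; ++j) {
      x.logE[j] = std::log(E[j]);
      x.logv[CH_PE][j] = std::log(std::max(pe[j], 1e-300));
      x.logv[CH_CO][j] = std::log(std::max(co[j], 1e-300));
      x.logv[CH_RA][j] = std::log(std::max(ra[j], 1e-300));
      x.logv[CH_TOT][j] = std::log(tot[j]);
      x.logv[CH_MUEN][j] = std::log(muen[j]);
    }
    x.emin = E[0]; x.emax = E[m - 1];
    List f = fflist[i];
    NumericVector fx = f["x"], f2 = f["f2"];
    FfTab& ff = M.ff[i];
    size_t k = fx.size();
    ff.x2.resize(k); ff.f2.resize(k); ff.cum.resize(k);
    for (size_t j = 0; j < k; ++j) { ff.x2[j] = fx[j] * fx[j]; ff.f2[j] = f2[j]; }
    ff.cum[0] = 0;
    for (size_t j = 1; j < k; ++j)
      ff.cum[j] = ff.cum[j - 1] +
        0.5 * (ff.f2[j] + ff.f2[j - 1]) * (ff.x2[j] - ff.x2[j - 1]);
  }
}

// [[Rcpp::export]]
List cpp_mc_run(List cfg) {
  Engine eng;
  load_materials(cfg["materials"], cfg["formfactors"], eng.mats);
  eng.tal.mats = &eng.mats;
  eng.cutoff = as<double>(cfg["cutoff"]);
  eng.majorant_margin = as<double>(cfg["majorant_margin"]);
  eng.primaries_only = as<bool>(cfg["primaries_only"]);

  // world
  List world = cfg["world"];
  std::string wt = as<std::string>(world["type"]);
  std::vector<int> phmat; std::vector<double> phrho;
  if (wt == "vacuum") {
    eng.wtype = W_VACUUM;
    if (world.containsElementNamed("horizon"))
      eng.world_R = as<double>(world["horizon"]);
  } else if (wt == "sphere") {
    eng.wtype = W_SPHERE;
    eng.sphere_R = as<double>(world["radius"]);
    eng.sphere_mat = as<int>(world["material"]);
  } else {
    eng.wtype = W_VOXEL;
    IntegerVector dim = world["dim"];
    NumericVector sp = world["spacing"], orig = world["origin"];
    IntegerVector mat = world["mat"];
    NumericVector rho = world["rho"];
    eng.ph.nx = dim[0]; eng.ph.ny = dim[1]; eng.ph.nz = dim[2];
    eng.ph.sx = sp[0]; eng.ph.sy = sp[1]; eng.ph.sz = sp[2];
    eng.ph.ox = orig[0]; eng.ph.oy = orig[1]; eng.ph.oz = orig[2];
    phmat.assign(mat.begin(), mat.end());
    phrho.assign(rho.begin(), rho.end());
    eng.ph.mat = phmat.data(); eng.ph.rho = phrho.data();
    // per-material maximum density for the Woodcock majorant
    eng.maj_cache.assign(eng.mats.xs.size(), 0.0);
    for (size_t v = 0; v < phmat.size(); ++v)
      if (phrho[v] > eng.maj_cache[phmat[v]]) eng.maj_cache[phmat[v]] = phrho[v];
  }

  // capsule
  if (cfg.containsElementNamed("capsule") &&
      !Rf_isNull(cfg["capsule"])) {
    List cp = cfg["capsule"];
    eng.caps.present = true;
    NumericVector o = cp["origin"];
    eng.caps.origin = {o[0], o[1], o[2]};
    eng.caps.rot = rot_from(cp["rotation"]);
    eng.caps.core_r = as<double>(cp["core_r"]);
    eng.caps.core_hl = as<double>(cp["core_hl"]);
    eng.caps.core_mat = as<int>(cp["core_mat"]);
    eng.caps.cap_r = as<double>(cp["cap_r"]);
    eng.caps.cap_hl = as<double>(cp["cap_hl"]);
    eng.caps.cap_mat = as<int>(cp["cap_mat"]);
    eng.caps.cable_r = as<double>(cp["cable_r"]);
    eng.caps.cable_len = as<double>(cp["cable_len"]);
    eng.caps.cable_mat = as<int>(cp["cable_mat"]);
  }

  // score grids
  std::vector<ScoreGrid> grids;
  List glist = cfg["grids"];
  grids.resize(glist.size());
  for (int gi = 0; gi < glist.size(); ++gi) {
    List g = glist[gi];
    ScoreGrid& sg = grids[gi];
    IntegerVector dim = g["dim"];
    NumericVector sp = g["spacing"], orig = g["origin"];
    sg.nx = dim[0]; sg.ny = dim[1]; sg.nz = dim[2];
    sg.sx = sp[0]; sg.sy = sp[1]; sg.sz = sp[2];
    sg.ox = orig[0]; sg.oy = orig[1]; sg.oz = orig[2];
    sg.vol = sg.sx * sg.sy * sg.sz;
    IntegerVector mat = g["mat"];
    sg.mat.assign(mat.begin(), mat.end());
    NumericVector rho = g["rho"];
    sg.rho.assign(rho.begin(), rho.end());
    sg.tlke = as<bool>(g["tlke"]);
    sg.analog = as<bool>(g["analog"]);
    size_t nv = sg.nvox();
    if (sg.tlke) { sg.t_sum.assign(nv, 0); sg.t_sumsq.assign(nv, 0); sg.t_buf.assign(nv, 0); }
    if (sg.analog) { sg.a_sum.assign(nv, 0); sg.a_sumsq.assign(nv, 0); sg.a_buf.assign(nv, 0); }
    eng.tal.grids.push_back(&sg);
  }

  std::vector<RingCell> rings;
  List rlist = cfg["rings"];
  rings.resize(rlist.size());
  for (int ri = 0; ri < rlist.size(); ++ri) {
    List r = rlist[ri];
    RingCell& rc = rings[ri];
    NumericVector o = r["origin"];
    rc.origin = {o[0], o[1], o[2]};
    rc.rot = rot_from(r["rotation"]);
    rc.r_in = as<double>(r["r_in"]); rc.r_out = as<double>(r["r_out"]);
    rc.half_h = as<double>(r["half_h"]); rc.mat = as<int>(r["material"]);
    rc.vol = M_PI * (rc.r_out * rc.r_out - rc.r_in * rc.r_in) * 2 * rc.half_h;
    eng.tal.rings.push_back(&rc);
  }

  // source
  List src = cfg["source"];
  std::string stype = as<std::string>(src["type"]);
  std::vector<double> specE, specCum;
  if (src.containsElementNamed("spectrum") && !Rf_isNull(src["spectrum"])) {
    NumericMatrix sp = src["spectrum"];
    double c = 0;
    for (int i = 0; i < sp.nrow(); ++i) {
      specE.push_back(sp(i, 0)); c += sp(i, 1); specCum.push_back(c);
    }
  }
  V3 spos = {0, 0, 0}, sdir = {0, 0, 1};
  double sE = 0;
  if (src.containsElementNamed("position")) {
    NumericVector p = src["position"]; spos = {p[0], p[1], p[2]};
  }
  if (src.containsElementNamed("direction")) {
    NumericVector d = src["direction"]; sdir = {d[0], d[1], d[2]};
  }
  if (src.containsElementNamed("energy") && !Rf_isNull(src["energy"]))
    sE = as<double>(src["energy"]);

  // plan source data
  NumericMatrix psf_rec, dwell_rot;
  NumericVector dwell_cum;
  NumericMatrix dwell_pos;
  int split = 1;
  if (stype == "plan") {
    psf_rec = as<NumericMatrix>(src["psf"]);
    dwell_pos = as<NumericMatrix>(src["dwell_pos"]);
    dwell_rot = as<NumericMatrix>(src["dwell_rot"]);   // n x 9 row-major
    NumericVector w = src["dwell_weights"];
    double c = 0; dwell_cum = NumericVector(w.size());
    for (int i = 0; i < w.size(); ++i) { c += w[i]; dwell_cum[i] = c; }
    split = as<int>(src["split"]);
  }

  eng.collect_psf = as<bool>(cfg["collect_psf"]);
  eng.psf_max = eng.collect_psf ? as<double>(cfg["psf_max"]) : 0;

  uint64_t seed0 = splitmix64((uint64_t)as<double>(cfg["seed"]));
  R_xlen_t nhist = (R_xlen_t)as<double>(cfg["histories"]);

  for (R_xlen_t h = 0; h < nhist; ++h) {
    Pcg32 rng; rng.seed(seed0, (uint64_t)h);
    bool any_int = false;
    double hist_emit = 0;
    double e0 = eng.E_escaped, d0 = eng.E_deposited;
    if (stype == "capsule") {
      Particle pt;
      double rr = eng.caps.core_r * std::sqrt(rng.u());
      double phi = 2 * M_PI * rng.u();
      double zz = (2 * rng.u() - 1) * eng.caps.core_hl;
      V3 pl = {rr * std::cos(phi), rr * std::sin(phi), zz};
      pt.p = eng.caps.origin + eng.caps.rot.toWorld(pl);
      iso_dir(rng, pt.d);
      pt.E = specE.size() ? sample_line(specCum, specE, rng) : sE;
      pt.wt = 1.0;
      hist_emit = pt.E;
      eng.E_emitted += pt.E;
      eng.track(pt, rng, any_int);
    } else if (stype == "point" || stype == "pencil") {
      Particle pt;
      pt.p = spos;
      if (stype == "point") iso_dir(rng, pt.d); else pt.d = sdir;
      pt.E = specE.size() ? sample_line(specCum, specE, rng) : sE;
      pt.wt = 1.0;
      hist_emit = pt.E;
      eng.E_emitted += pt.E;
      eng.track(pt, rng, any_int);
    } else {  // plan: one PSF record per history, split clones
      int rec = (int)(h % psf_rec.nrow());
      double wt = 1.0 / split;
      for (int sgi = 0; sgi < split; ++sgi) {
        // dwell selection by cumulative time weights
        double u = rng.u() * dwell_cum[dwell_cum.size() - 1];
        int lo = 0, hi = dwell_cum.size() - 1;
        while (hi > lo) { int m = (lo + hi) / 2; if (dwell_cum[m] < u) lo = m + 1; else hi = m; }
        Rot R;
        for (int q = 0; q < 9; ++q) R.m[q] = dwell_rot(lo, q);
        V3 rp = {psf_rec(rec, 1), psf_rec(rec, 2), psf_rec(rec, 3)};
        V3 rd = {psf_rec(rec, 4), psf_rec(rec, 5), psf_rec(rec, 6)};
        Particle pt;
        pt.p = V3{dwell_pos(lo, 0), dwell_pos(lo, 1), dwell_pos(lo, 2)} + R.toWorld(rp);
        pt.d = R.toWorld(rd);
        pt.E = psf_rec(rec, 0);
        pt.wt = wt * psf_rec(rec, 7);
        hist_emit += pt.wt * pt.E;
        eng.E_emitted += pt.wt * pt.E;
        eng.track(pt, rng, any_int);
      }
    }
    if (!any_int) eng.n_uncollided += 1;
    double resid = std::fabs(hist_emit - (eng.E_escaped - e0) -
                             (eng.E_deposited - d0));
    if (hist_emit > 0) resid /= hist_emit;
    if (resid > eng.max_resid) eng.max_resid = resid;
    eng.tal.flush();
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List gout(grids.size());
  for (size_t gi = 0; gi < grids.size(); ++gi) {
    ScoreGrid& g = grids[gi];
    List o = List::create(
      _["tlke_sum"] = g.tlke ? NumericVector(g.t_sum.begin(), g.t_sum.end()) : NumericVector(0),
      _["tlke_sumsq"] = g.tlke ? NumericVector(g.t_sumsq.begin(), g.t_sumsq.end()) : NumericVector(0),
      _["analog_sum"] = g.analog ? NumericVector(g.a_sum.begin(), g.a_sum.end()) : NumericVector(0),
      _["analog_sumsq"] = g.analog ? NumericVector(g.a_sumsq.begin(), g.a_sumsq.end()) : NumericVector(0));
    gout[gi] = o;
  }
  List rout(rings.size());
  for (size_t ri = 0; ri < rings.size(); ++ri)
    rout[ri] = List::create(_["sum"] = rings[ri].sum,
                            _["sumsq"] = rings[ri].sumsq);
  NumericMatrix psfm(eng.psf.size() / 8, 8);
  for (size_t i = 0; i < eng.psf.size() / 8; ++i)
    for (int j = 0; j < 8; ++j) psfm(i, j) = eng.psf[8 * i + j];

  return List::create(
    _["grids"] = gout, _["rings"] = rout,
    _["n_histories"] = (double)nhist,
    _["emitted"] = eng.E_emitted, _["escaped"] = eng.E_escaped,
    _["deposited"] = eng.E_deposited,
    _["max_conservation_residual"] = eng.max_resid,
    _["n_uncollided"] = eng.n_uncollided,
    _["psf"] = psfm);
}

// exact voxel traversal of a segment, exposed for the tally test surface
// [[Rcpp::export]]
List cpp_siddon(NumericVector p0, NumericVector p1, IntegerVector dim,
                NumericVector spacing, NumericVector origin) {
  ScoreGrid g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  V3 a = {p0[0], p0[1], p0[2]}, b = {p1[0], p1[1], p1[2]};
  V3 dvec = b - a;
  double L = std::sqrt(dot(dvec, dvec));
  std::vector<int> vi, vj, vk; std::vector<double> vl;
  if (L > 0) {
    V3 d = (1.0 / L) * dvec;
    // local reimplementation of the walk that records voxels
    double t0 = 0.0, t1 = L;
    double lo[3] = {g.ox, g.oy, g.oz};
    double hi[3] = {g.ox + g.nx * g.sx, g.oy + g.ny * g.sy, g.oz + g.nz * g.sz};
    double pp[3] = {a.x, a.y, a.z}, dd[3] = {d.x, d.y, d.z};
    bool miss = false;
    for (int ax = 0; ax < 3; ++ax) {
      if (std::fabs(dd[ax]) < 1e-14) {
        if (pp[ax] <= lo[ax] || pp[ax] >= hi[ax]) miss = true;
      } else {
        double u0 = (lo[ax] - pp[ax]) / dd[ax], u1 = (hi[ax] - pp[ax]) / dd[ax];
        if (u0 > u1) std::swap(u0, u1);
        t0 = std::max(t0, u0); t1 = std::min(t1, u1);
      }
    }
    if (!miss && t1 > t0) {
      double t = t0 + 1e-12 * (t1 - t0);
      V3 q = a + t * d;
      int i = (int)std::floor((q.x - g.ox) / g.sx);
      int j = (int)std::floor((q.y - g.oy) / g.sy);
      int k = (int)std::floor((q.z - g.oz) / g.sz);
      i = std::min(std::max(i, 0), g.nx - 1);
      j = std::min(std::max(j, 0), g.ny - 1);
      k = std::min(std::max(k, 0), g.nz - 1);
      int si = dd[0] > 0 ? 1 : -1, sj = dd[1] > 0 ? 1 : -1, sk = dd[2] > 0 ? 1 : -1;
      double tx = (std::fabs(dd[0]) < 1e-14) ? INF :
        ((g.ox + (i + (si > 0 ? 1 : 0)) * g.sx) - pp[0]) / dd[0];
      double ty = (std::fabs(dd[1]) < 1e-14) ? INF :
        ((g.oy + (j + (sj > 0 ? 1 : 0)) * g.sy) - pp[1]) / dd[1];
      double tz = (std::fabs(dd[2]) < 1e-14) ? INF :
        ((g.oz + (k + (sk > 0 ? 1 : 0)) * g.sz) - pp[2]) / dd[2];
      double dtx = std::fabs(g.sx / dd[0]), dty = std::fabs(g.sy / dd[1]),
             dtz = std::fabs(g.sz / dd[2]);
      double tc = t0;
      while (tc < t1 - 1e-13) {
        double tn = std::min(std::min(tx, ty), std::min(tz, t1));
        double len = tn - tc;
        if (len > 1e-12) {
          vi.push_back(i + 1); vj.push_back(j + 1); vk.push_back(k + 1);
          vl.push_back(len);
        }
        if (tn >= t1 - 1e-13) break;
        if (tx <= ty && tx <= tz) { i += si; tx += dtx; }
        else if (ty <= tz) { j += sj; ty += dty; }
        else { k += sk; tz += dtz; }
        if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz) break;
        tc = tn;
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["k"] = wrap(vk),
                      _["length"] = wrap(vl));
}

// analytic chord of a segment through an annular cylinder cell
// [[Rcpp::export]]
double cpp_cyl_chord(NumericVector p0, NumericVector p1, NumericVector origin,
                     NumericMatrix rotation, double r_in, double r_out,
                     double half_h) {
  RingCell rc;
  rc.origin = {origin[0], origin[1], origin[2]};
  rc.rot = rot_from(rotation);
  rc.r_in = r_in; rc.r_out = r_out; rc.half_h = half_h;
  V3 a = {p0[0], p0[1], p0[2]}, b = {p1[0], p1[1], p1[2]};
  V3 dv = b - a;
  double L = std::sqrt(dot(dv, dv));
  if (L == 0) return 0.0;
  return rc.chord(a, (1.0 / L) * dv, L);
}

// Klein-Nishina sampler exposed for the transport test surface
// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E, int n, double seed) {
  NumericMatrix out(n, 2);
  Pcg32 rng; rng.seed(splitmix64((uint64_t)seed), 0x9E37u);
  for (int i = 0; i < n; ++i) {
    double Ep, c;
    sample_compton(E, rng, Ep, c);
    out(i, 0) = Ep; out(i, 1) = c;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_rayleigh(double E, int n, double seed,
                                  NumericVector ffx, NumericVector ff2) {
  FfTab ff;
  size_t k = ffx.size();
  ff.x2.resize(k); ff.f2.resize(k); ff.cum.resize(k);
  for (size_t j = 0; j < k; ++j) { ff.x2[j] = ffx[j] * ffx[j]; ff.f2[j] = ff2[j]; }
  ff.cum[0] = 0;
  for (size_t j = 1; j < k; ++j)
    ff.cum[j] = ff.cum[j - 1] + 0.5 * (ff.f2[j] + ff.f2[j - 1]) * (ff.x2[j] - ff.x2[j - 1]);
  NumericVector out(n);
  Pcg32 rng; rng.seed(splitmix64((uint64_t)seed), 0xA511u);
  for (int i = 0; i < n; ++i) out[i] = sample_rayleigh(ff, E, rng);
  return out;
}

// raw capsule-core emission states (position uniform in core, isotropic
// direction, spectrum-sampled energy), for the source test surface
// [[Rcpp::export]]
NumericMatrix cpp_emit(double core_r, double core_hl, NumericMatrix spectrum,
                       int n, double seed) {
  std::vector<double> specE, specCum;
  double c = 0;
  for (int i = 0; i < spectrum.nrow(); ++i) {
    specE.push_back(spectrum(i, 0)); c += spectrum(i, 1); specCum.push_back(c);
  }
  NumericMatrix out(n, 7);
  Pcg32 rng; rng.seed(splitmix64((uint64_t)seed), 0xE317u);
  for (int i = 0; i < n; ++i) {
    double rr = core_r * std::sqrt(rng.u());
    double phi = 2 * M_PI * rng.u();
    double zz = (2 * rng.u() - 1) * core_hl;
    V3 d; iso_dir(rng, d);
    out(i, 0) = sample_line(specCum, specE, rng);
    out(i, 1) = rr * std::cos(phi); out(i, 2) = rr * std::sin(phi);
    out(i, 3) = zz;
    out(i, 4) = d.x; out(i, 5) = d.y; out(i, 6) = d.z;
  }
  return out;
}
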