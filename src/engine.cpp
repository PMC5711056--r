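// Analog photon Monte Carlo engine: emission sampling from dwell cylinders,
// ray-traced transport through phantom/air/steel-wire geometry, and
// kerma-proportional scoring (track-length and collision estimators).
// Optical-depth bookkeeping crosses material boundaries without extra RNG
// draws, so paired-geometry runs (common random numbers) stay correlated.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double ME = 0.510998928;    // electron rest energy, MeV
static const double RE2 = 7.9407877e-26; // classical electron radius squared, cm^2
static const double EPS = 1e-6;          // boundary push, cm
static const double INF = 1e30;

// ---------- RNG: xoshiro256++ seeded through splitmix64 ----------
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t v) {
    uint64_t x = v;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97f4A7C15ULL;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double u() { return (next() >> 11) * 1.1102230246251565e-16; } // [0,1)
  double u_pos() { double v = 1.0 - u(); return v; }             // (0,1]
};

// ---------- cross-section table (log-log interpolation) ----------
struct XsTab {
  std::vector<double> lE, ltot, lwoc, len;
  double ne, rho;
  void init(const NumericMatrix &m, double ne_, double rho_) {
    ne = ne_; rho = rho_;
    int n = m.nrow();
    lE.resize(n); ltot.resize(n); lwoc.resize(n); len.resize(n);
    for (int i = 0; i < n; ++i) {
      lE[i] = std::log(m(i, 0));
      ltot[i] = std::log(m(i, 1));
      lwoc[i] = std::log(m(i, 2));
      len[i] = std::log(m(i, 3));
    }
  }
  double interp(const std::vector<double> &col, double E) const {
    double x = std::log(E);
    int n = (int)lE.size();
    if (x <= lE[0]) return std::exp(col[0]);
    if (x >= lE[n - 1]) return std::exp(col[n - 1]);
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; (lE[mid] <= x ? lo : hi) = mid; }
    double f = (x - lE[lo]) / (lE[lo + 1] - lE[lo]);
    return std::exp(col[lo] * (1 - f) + col[lo + 1] * f);
  }
  double mu_tot(double E) const { return interp(ltot, E); }
  double mu_woc(double E) const { return interp(lwoc, E); }
  double muen(double E) const { return interp(len, E); }
};

// ---------- Klein-Nishina ----------
static double kn_sigma(double E) {
  double a = E / ME;
  double t1 = (1 + a) / (a * a) * (2 * (1 + a) / (1 + 2 * a) - std::log(1 + 2 * a) / a);
  double t2 = std::log(1 + 2 * a) / (2 * a);
  double t3 = (1 + 3 * a) / ((1 + 2 * a) * (1 + 2 * a));
  return 2 * M_PI * RE2 * (t1 + t2 - t3);
}

// Kahn's composition-rejection sampling of the Klein-Nishina distribution.
static void kn_sample(double E, Rng &g, double &Eout, double &cosT) {
  double a = E / ME, x;
  for (;;) {
    double r1 = g.u(), r2 = g.u(), r3 = g.u();
    if (r1 <= (1 + 2 * a) / (9 + 2 * a)) {
      x = 1 + 2 * a * r2;
      if (r3 <= 4 * (1 / x - 1 / (x * x))) break;
    } else {
      x = (1 + 2 * a) / (1 + 2 * a * r2);
      double m = 1 + (1 - x) / a;
      if (r3 <= 0.5 * (m * m + 1 / x)) break;
    }
  }
  Eout = E / x;
  cosT = 1 + (1 - x) / a;
}

// ---------- small vector helpers ----------
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 add(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 sub(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 scl(V3 a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// orthonormal basis perpendicular to unit vector w
static void basis(V3 w, V3 &u, V3 &v) {
  if (std::fabs(w.z) < 0.9) u = v3(-w.y, w.x, 0.0);
  else u = v3(0.0, -w.z, w.y);
  double n = std::sqrt(dot(u, u));
  u = scl(u, 1.0 / n);
  v = v3(w.y * u.z - w.z * u.y, w.z * u.x - w.x * u.z, w.x * u.y - w.y * u.x);
}

static V3 rotate_dir(V3 d, double cosT, double phi, Rng &) {
  double sinT = std::sqrt(std::max(0.0, 1.0 - cosT * cosT));
  V3 u, v;
  basis(d, u, v);
  return v3(d.x * cosT + sinT * (u.x * std::cos(phi) + v.x * std::sin(phi)),
            d.y * cosT + sinT * (u.y * std::cos(phi) + v.y * std::sin(phi)),
            d.z * cosT + sinT * (u.z * std::cos(phi) + v.z * std::sin(phi)));
}

// ---------- geometry ----------
struct Wire { V3 p0; V3 ax; double h, r; };

struct Scene {
  int phantom_kind;        // 0 = cuboid, 1 = sphere, 2 = none (vacuum/air world)
  V3 box_lo, box_hi;
  double sphere_r;
  double world_half;
  bool vacuum;             // true: no interactions anywhere inside the world
  std::vector<Wire> wires;
  bool has_wires;
  double wire_bound_r;     // bounding sphere radius around origin for wires
  std::vector<Wire> srcs;  // attenuating source (iridium) cylinders
  bool src_att;
  double src_bound_r;

  bool inside_world(V3 p) const {
    return std::fabs(p.x) <= world_half && std::fabs(p.y) <= world_half &&
           std::fabs(p.z) <= world_half;
  }
  bool inside_phantom(V3 p) const {
    if (phantom_kind == 0)
      return p.x >= box_lo.x && p.x <= box_hi.x && p.y >= box_lo.y &&
             p.y <= box_hi.y && p.z >= box_lo.z && p.z <= box_hi.z;
    if (phantom_kind == 1) return dot(p, p) <= sphere_r * sphere_r;
    return false;
  }
  static bool inside_cyls(const std::vector<Wire> &cyl, V3 p) {
    for (size_t i = 0; i < cyl.size(); ++i) {
      V3 q = sub(p, cyl[i].p0);
      double s = dot(q, cyl[i].ax);
      if (s < 0 || s > cyl[i].h) continue;
      V3 perp = sub(q, scl(cyl[i].ax, s));
      if (dot(perp, perp) <= cyl[i].r * cyl[i].r) return true;
    }
    return false;
  }
  // material codes: 0 water, 1 air, 2 steel, 3 outside world, 4 vacuum,
  // 5 iridium (source)
  int material_at(V3 p) const {
    if (!inside_world(p)) return 3;
    if (vacuum) return 4;
    if (src_att && dot(p, p) <= src_bound_r * src_bound_r &&
        inside_cyls(srcs, p)) return 5;
    if (has_wires && inside_cyls(wires, p)) return 2;
    if (inside_phantom(p)) return 0;
    return 1;
  }
};

// candidate boundary crossings -> nearest t > tmin
static void box_cross(V3 p, V3 d, V3 lo, V3 hi, double &best) {
  double t1, t2;
  const double tmin = 1e-7;
  // slab per axis; record both crossing parameters where the point is on the face
  double los[3] = {lo.x, lo.y, lo.z}, his[3] = {hi.x, hi.y, hi.z};
  double ps[3] = {p.x, p.y, p.z}, ds[3] = {d.x, d.y, d.z};
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(ds[ax]) < 1e-14) continue;
    for (int side = 0; side < 2; ++side) {
      double plane = side ? his[ax] : los[ax];
      double t = (plane - ps[ax]) / ds[ax];
      if (t <= tmin || t >= best) continue;
      bool on = true;
      for (int k = 0; k < 3; ++k) {
        if (k == ax) continue;
        double c = ps[k] + t * ds[k];
        if (c < los[k] - 1e-9 || c > his[k] + 1e-9) { on = false; break; }
      }
      if (on) best = t;
    }
  }
  (void)t1; (void)t2;
}

static void sphere_cross(V3 p, V3 d, V3 c, double R, double &best) {
  V3 q = sub(p, c);
  double b = dot(q, d);
  double cc = dot(q, q) - R * R;
  double disc = b * b - cc;
  if (disc <= 0) return;
  double sq = std::sqrt(disc);
  double t1 = -b - sq, t2 = -b + sq;
  const double tmin = 1e-7;
  if (t1 > tmin && t1 < best) best = t1;
  if (t2 > tmin && t2 < best) best = t2;
}

static void wire_cross(V3 p, V3 d, const Wire &w, double &best) {
  const double tmin = 1e-7;
  V3 q = sub(p, w.p0);
  double qa = dot(q, w.ax), da = dot(d, w.ax);
  // lateral surface
  double A = 1.0 - da * da;
  double B = dot(q, d) - qa * da;
  double C = dot(q, q) - qa * qa - w.r * w.r;
  if (A > 1e-14) {
    double disc = B * B - A * C;
    if (disc > 0) {
      double sq = std::sqrt(disc);
      for (int s = -1; s <= 1; s += 2) {
        double t = (-B + s * sq) / A;
        if (t <= tmin || t >= best) continue;
        double ss = qa + t * da;
        if (ss >= 0 && ss <= w.h) best = t;
      }
    }
  }
  // caps
  if (std::fabs(da) > 1e-14) {
    for (int side = 0; side < 2; ++side) {
      double plane = side ? w.h : 0.0;
      double t = (plane - qa) / da;
      if (t <= tmin || t >= best) continue;
      V3 at = add(q, scl(d, t));
      V3 perp = sub(at, scl(w.ax, dot(at, w.ax)));
      if (dot(perp, perp) <= w.r * w.r) best = t;
    }
  }
}

static double boundary_distance(const Scene &sc, V3 p, V3 d) {
  double best = INF;
  V3 wl = v3(-sc.world_half, -sc.world_half, -sc.world_half);
  V3 wh = v3(sc.world_half, sc.world_half, sc.world_half);
  box_cross(p, d, wl, wh, best);
  if (sc.phantom_kind == 0) box_cross(p, d, sc.box_lo, sc.box_hi, best);
  else if (sc.phantom_kind == 1) sphere_cross(p, d, v3(0, 0, 0), sc.sphere_r, best);
  if (sc.has_wires) {
    double bb = INF;
    sphere_cross(p, d, v3(0, 0, 0), sc.wire_bound_r, bb);
    bool near_inside = dot(p, p) <= sc.wire_bound_r * sc.wire_bound_r;
    if (near_inside || bb < best)
      for (size_t i = 0; i < sc.wires.size(); ++i) wire_cross(p, d, sc.wires[i], best);
  }
  if (sc.src_att) {
    double bb = INF;
    sphere_cross(p, d, v3(0, 0, 0), sc.src_bound_r, bb);
    bool near_inside = dot(p, p) <= sc.src_bound_r * sc.src_bound_r;
    if (near_inside || bb < best)
      for (size_t i = 0; i < sc.srcs.size(); ++i) wire_cross(p, d, sc.srcs[i], best);
  }
  return best;
}

// segment [0, t] along (p, d) clipped to sphere (c, R) -> overlap length
static double clip_sphere(V3 p, V3 d, double t, V3 c, double R) {
  V3 q = sub(p, c);
  double b = dot(q, d);
  double cc = dot(q, q) - R * R;
  double disc = b * b - cc;
  if (disc <= 0) return 0.0;
  double sq = std::sqrt(disc);
  double t1 = std::max(-b - sq, 0.0), t2 = std::min(-b + sq, t);
  return t2 > t1 ? t2 - t1 : 0.0;
}

// ---------- scene construction from R lists ----------
static Scene make_scene(List scene) {
  Scene sc;
  sc.phantom_kind = as<int>(scene["phantom_kind"]);
  NumericVector lo = scene["box_lo"], hi = scene["box_hi"];
  sc.box_lo = v3(lo[0], lo[1], lo[2]);
  sc.box_hi = v3(hi[0], hi[1], hi[2]);
  sc.sphere_r = as<double>(scene["sphere_r"]);
  sc.world_half = as<double>(scene["world_half"]);
  sc.vacuum = as<bool>(scene["vacuum"]);
  NumericMatrix wm = scene["wires"];
  sc.has_wires = wm.nrow() > 0;
  sc.wire_bound_r = 0.0;
  for (int i = 0; i < wm.nrow(); ++i) {
    Wire w;
    w.p0 = v3(wm(i, 0), wm(i, 1), wm(i, 2));
    V3 p1 = v3(wm(i, 3), wm(i, 4), wm(i, 5));
    V3 ax = sub(p1, w.p0);
    w.h = std::sqrt(dot(ax, ax));
    w.ax = scl(ax, 1.0 / w.h);
    w.r = wm(i, 6);
    sc.wires.push_back(w);
    double e0 = std::sqrt(dot(w.p0, w.p0)) + w.r;
    double e1 = std::sqrt(dot(p1, p1)) + w.r;
    sc.wire_bound_r = std::max(sc.wire_bound_r, std::max(e0, e1) + 0.01);
  }
  // attenuating source cylinders built from the dwell set
  sc.src_att = as<bool>(scene["source_attenuation"]);
  sc.src_bound_r = 0.0;
  if (sc.src_att) {
    NumericMatrix dc = scene["dwell_centers"], da = scene["dwell_axes"];
    double half = as<double>(scene["dwell_half"]);
    double rad = as<double>(scene["dwell_radius"]);
    for (int i = 0; i < dc.nrow(); ++i) {
      Wire w;
      V3 c = v3(dc(i, 0), dc(i, 1), dc(i, 2));
      w.ax = v3(da(i, 0), da(i, 1), da(i, 2));
      w.p0 = sub(c, scl(w.ax, half));
      w.h = 2 * half;
      w.r = rad;
      sc.srcs.push_back(w);
      double e = std::sqrt(dot(c, c)) + half + rad;
      sc.src_bound_r = std::max(sc.src_bound_r, e + 0.01);
    }
  }
  return sc;
}

struct Mats { XsTab water, air, steel, iridium; };
static Mats make_mats(List xs) {
  Mats m;
  List w = xs["water"], a = xs["air"], s = xs["steel"], ir = xs["iridium"];
  m.water.init(as<NumericMatrix>(w["table"]), as<double>(w["ne"]), as<double>(w["rho"]));
  m.air.init(as<NumericMatrix>(a["table"]), as<double>(a["ne"]), as<double>(a["rho"]));
  m.steel.init(as<NumericMatrix>(s["table"]), as<double>(s["ne"]), as<double>(s["rho"]));
  m.iridium.init(as<NumericMatrix>(ir["table"]), as<double>(ir["ne"]), as<double>(ir["rho"]));
  return m;
}
static const XsTab *mat_tab(const Mats &m, int code) {
  if (code == 0) return &m.water;
  if (code == 1) return &m.air;
  if (code == 2) return &m.steel;
  if (code == 5) return &m.iridium;
  return 0;
}

// ---------- transport of one photon ----------
struct TallyCtx {
  const std::vector<V3> *det_c;
  const std::vector<double> *det_R;
  double *track;   // per detector accumulators for current (dwell, batch)
  double *coll;
  // kernel-mode scatter scoring
  bool kernel_mode;
  const std::vector<double> *r_edges;   // ascending
  const std::vector<double> *ct_edges;  // ascending cos(theta) edges
  double *kern;   // [nr x nct] accumulator for current batch
  int nr, nct;
  // pencil-mode first-collision depth
  double *first_depth;
  bool record_first;
};

static void transport(const Scene &sc, const Mats &mats, V3 pos, V3 dir,
                      double E, double cutoff, bool coherent, Rng &g,
                      TallyCtx &tc) {
  int nscat = 0;
  double straight = 0.0;  // distance along the initial flight (pencil mode)
  double tau = -std::log(g.u_pos());
  int guard = 0;
  for (;;) {
    if (++guard > 100000) break;
    int mat = sc.material_at(pos);
    if (mat == 3) break;
    double mu_lin = 0.0;
    const XsTab *tab = mat_tab(mats, mat);
    if (tab) {
      double mu_rho = coherent ? tab->mu_tot(E) : tab->mu_woc(E);
      mu_lin = mu_rho * tab->rho;
    }
    double d_col = mu_lin > 0 ? tau / mu_lin : INF;
    double d_b = boundary_distance(sc, pos, dir);
    double step = std::min(d_col, d_b);
    if (step >= INF) break;
    // track-length scoring over this segment
    for (size_t k = 0; k < tc.det_c->size(); ++k) {
      double L = clip_sphere(pos, dir, step, (*tc.det_c)[k], (*tc.det_R)[k]);
      if (L > 0) tc.track[k] += L * E * mats.water.muen(E);
    }
    if (d_col < d_b) {
      pos = add(pos, scl(dir, d_col));
      if (tc.record_first && nscat == 0 && tc.first_depth)
        *tc.first_depth = straight + d_col;
      // collision estimator (kerma to water), scored before sampling the event
      for (size_t k = 0; k < tc.det_c->size(); ++k) {
        V3 q = sub(pos, (*tc.det_c)[k]);
        double R = (*tc.det_R)[k];
        if (dot(q, q) <= R * R) tc.coll[k] += E * mats.water.muen(E) / mu_lin;
      }
      if (tc.kernel_mode && mat == 0) {
        double r = std::sqrt(dot(pos, pos));
        if (r > 1e-12) {
          double ct = pos.z / r;
          const std::vector<double> &re = *tc.r_edges, &ce = *tc.ct_edges;
          if (r >= re.front() && r < re.back() && ct >= ce.front() && ct <= ce.back()) {
            int ir = (int)(std::upper_bound(re.begin(), re.end(), r) - re.begin()) - 1;
            int ic = (int)(std::upper_bound(ce.begin(), ce.end(), ct) - ce.begin()) - 1;
            if (ic == tc.nct) ic--;
            if (ir >= 0 && ir < tc.nr && ic >= 0 && ic < tc.nct)
              tc.kern[ir + tc.nr * ic] += E * mats.water.muen(E) / mu_lin;
          }
        }
      }
      // event sampling
      const XsTab *t2 = mat_tab(mats, mat);
      double mu_rho_used = coherent ? t2->mu_tot(E) : t2->mu_woc(E);
      double p_compton = std::min(1.0, t2->ne * kn_sigma(E) / mu_rho_used);
      double u = g.u();
      if (u < p_compton) {
        double Eout, cosT;
        kn_sample(E, g, Eout, cosT);
        dir = rotate_dir(dir, cosT, 2 * M_PI * g.u(), g);
        E = Eout;
        nscat++;
        if (E < cutoff) break;
      } else if (coherent &&
                 u < p_compton + std::max(0.0, (t2->mu_tot(E) - t2->mu_woc(E)) / t2->mu_tot(E))) {
        // coherent scatter: Thomson-shaped deflection, energy unchanged
        double m, v;
        do { m = 2 * g.u() - 1; v = g.u(); } while (v > 0.5 * (1 + m * m));
        dir = rotate_dir(dir, m, 2 * M_PI * g.u(), g);
        nscat++;
      } else {
        break; // absorbed (photoelectric / pair treated as local absorption)
      }
      tau = -std::log(g.u_pos());
    } else {
      pos = add(pos, scl(dir, d_b + EPS));
      tau -= mu_lin * (d_b + EPS);
      if (tau < 0) tau = 0;
      if (nscat == 0) straight += d_b + EPS;
    }
  }
}

// sample a discrete line from cumulative pmf
static double sample_line(const std::vector<double> &cum,
                          const std::vector<double> &En, Rng &g) {
  double u = g.u();
  int n = (int)cum.size();
  int lo = 0, hi = n - 1;
  if (u <= cum[0]) return En[0];
  while (hi - lo > 1) { int mid = (lo + hi) / 2; (cum[mid] < u ? lo : hi) = mid; }
  return En[hi];
}

// ---------- main tally engine ----------
// [[Rcpp::export]]
List mc_run_cpp(List scene, List cfg, List xs) {
  Scene sc = make_scene(scene);
  Mats mats = make_mats(xs);

  NumericMatrix dwc = scene["dwell_centers"], dwa = scene["dwell_axes"];
  double dw_half = as<double>(scene["dwell_half"]);
  double dw_rad = as<double>(scene["dwell_radius"]);
  int ndw = dwc.nrow();

  NumericMatrix det = scene["detectors"]; // x,y,z,R
  int ndet = det.nrow();
  std::vector<V3> det_c(ndet);
  std::vector<double> det_R(ndet);
  for (int k = 0; k < ndet; ++k) { det_c[k] = v3(det(k,0), det(k,1), det(k,2)); det_R[k] = det(k,3); }

  int n_per = as<int>(cfg["n_per_dwell"]);
  int nbatch = as<int>(cfg["n_batches"]);
  uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  double cutoff = as<double>(cfg["cutoff"]);
  bool coherent = as<bool>(cfg["coherent"]);
  int mode = as<int>(cfg["source_mode"]); // 0 dwells, 1 point isotropic, 2 pencil
  NumericVector spos = cfg["source_pos"], sdir = cfg["source_dir"];
  bool record_first = as<bool>(cfg["record_first"]);

  NumericMatrix spm = cfg["spectrum"]; // energy, pmf
  int nl = spm.nrow();
  std::vector<double> En(nl), cum(nl);
  double acc = 0;
  for (int i = 0; i < nl; ++i) { acc += spm(i, 1); En[i] = spm(i, 0); cum[i] = acc; }
  for (int i = 0; i < nl; ++i) cum[i] /= acc;

  int nsrc = (mode == 0) ? ndw : 1;
  // accumulators [src][batch][det]
  NumericVector track(nsrc * nbatch * ndet), coll(nsrc * nbatch * ndet);
  std::vector<double> first_depths;
  if (record_first) first_depths.reserve((size_t)n_per * nbatch);

  std::vector<double> dummy_edges;
  for (int i = 0; i < nsrc; ++i) {
    V3 c = v3(0, 0, 0), ax = v3(0, 0, 1);
    if (mode == 0) {
      c = v3(dwc(i, 0), dwc(i, 1), dwc(i, 2));
      ax = v3(dwa(i, 0), dwa(i, 1), dwa(i, 2));
    } else {
      c = v3(spos[0], spos[1], spos[2]);
    }
    V3 u1, u2;
    basis(ax, u1, u2);
    for (int b = 0; b < nbatch; ++b) {
      Rng g;
      g.seed(seed * 0x100000001B3ULL + (uint64_t)(i * 1048576 + b + 1));
      TallyCtx tc;
      double dummy = 0;
      tc.det_c = &det_c; tc.det_R = &det_R;
      tc.track = ndet ? &track[(i * nbatch + b) * ndet] : &dummy;
      tc.coll = ndet ? &coll[(i * nbatch + b) * ndet] : &dummy;
      tc.kernel_mode = false; tc.r_edges = &dummy_edges; tc.ct_edges = &dummy_edges;
      tc.kern = 0; tc.nr = 0; tc.nct = 0;
      tc.record_first = record_first;
      for (int h = 0; h < n_per; ++h) {
        V3 pos, dir;
        if (mode == 0) {
          double zz = (2 * g.u() - 1) * dw_half;
          double rr = dw_rad * std::sqrt(g.u());
          double ph = 2 * M_PI * g.u();
          pos = add(c, add(scl(ax, zz),
                    add(scl(u1, rr * std::cos(ph)), scl(u2, rr * std::sin(ph)))));
        } else pos = c;
        if (mode == 2) dir = v3(sdir[0], sdir[1], sdir[2]);
        else {
          double ct = 2 * g.u() - 1, ph = 2 * M_PI * g.u();
          double st = std::sqrt(std::max(0.0, 1 - ct * ct));
          dir = v3(st * std::cos(ph), st * std::sin(ph), ct);
        }
        double E = sample_line(cum, En, g);
        double fd = INF;
        tc.first_depth = &fd;
        transport(sc, mats, pos, dir, E, cutoff, coherent, g, tc);
        if (record_first) first_depths.push_back(fd);
        if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
      }
    }
  }
  List out = List::create(
    _["track"] = track, _["coll"] = coll,
    _["n_src"] = nsrc, _["n_batches"] = nbatch, _["n_det"] = ndet,
    _["n_per_dwell"] = n_per);
  if (record_first) out["first_depths"] = NumericVector(first_depths.begin(), first_depths.end());
  return out;
}

// ---------- kernel scorer: single dwell at origin in full-scatter water ----------
// [[Rcpp::export]]
List mc_kernel_cpp(List cfg, List xs, NumericVector r_edges, NumericVector ct_edges,
                   double sphere_radius, double dwell_half, double dwell_radius,
                   bool source_attenuation) {
  Scene sc;
  sc.phantom_kind = 1;
  sc.sphere_r = sphere_radius;
  sc.world_half = std::max(50.0, sphere_radius);
  sc.vacuum = false;
  sc.has_wires = false;
  sc.box_lo = v3(0, 0, 0); sc.box_hi = v3(0, 0, 0);
  sc.src_att = source_attenuation;
  sc.src_bound_r = dwell_half + dwell_radius + 0.01;
  if (source_attenuation) {
    Wire w;
    w.p0 = v3(0, 0, -dwell_half);
    w.ax = v3(0, 0, 1);
    w.h = 2 * dwell_half;
    w.r = dwell_radius;
    sc.srcs.push_back(w);
  }
  Mats mats = make_mats(xs);

  int n_per = as<int>(cfg["n_per_dwell"]);
  int nbatch = as<int>(cfg["n_batches"]);
  uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  double cutoff = as<double>(cfg["cutoff"]);
  bool coherent = as<bool>(cfg["coherent"]);
  NumericMatrix spm = cfg["spectrum"];
  int nl = spm.nrow();
  std::vector<double> En(nl), cum(nl);
  double acc = 0;
  for (int i = 0; i < nl; ++i) { acc += spm(i, 1); En[i] = spm(i, 0); cum[i] = acc; }
  for (int i = 0; i < nl; ++i) cum[i] /= acc;

  std::vector<double> re(r_edges.begin(), r_edges.end());
  std::vector<double> ce(ct_edges.begin(), ct_edges.end());
  int nr = (int)re.size() - 1, nct = (int)ce.size() - 1;
  NumericVector kern(nr * nct * nbatch);
  std::vector<V3> det_c; std::vector<double> det_R; // no point detectors here

  V3 ax = v3(0, 0, 1), u1, u2;
  basis(ax, u1, u2);
  for (int b = 0; b < nbatch; ++b) {
    Rng g;
    g.seed(seed * 0x100000001B3ULL + (uint64_t)(b + 1));
    TallyCtx tc;
    tc.det_c = &det_c; tc.det_R = &det_R;
    tc.track = 0; tc.coll = 0;
    tc.kernel_mode = true;
    tc.r_edges = &re; tc.ct_edges = &ce;
    tc.kern = &kern[b * nr * nct];
    tc.nr = nr; tc.nct = nct;
    tc.record_first = false; tc.first_depth = 0;
    for (int h = 0; h < n_per; ++h) {
      double zz = (2 * g.u() - 1) * dwell_half;
      double rr = dwell_radius * std::sqrt(g.u());
      double ph = 2 * M_PI * g.u();
      V3 pos = add(scl(ax, zz), add(scl(u1, rr * std::cos(ph)), scl(u2, rr * std::sin(ph))));
      double ct = 2 * g.u() - 1, p2 = 2 * M_PI * g.u();
      double st = std::sqrt(std::max(0.0, 1 - ct * ct));
      V3 dir = v3(st * std::cos(p2), st * std::sin(p2), ct);
      double E = sample_line(cum, En, g);
      transport(sc, mats, pos, dir, E, cutoff, coherent, g, tc);
      if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["kern"] = kern, _["nr"] = nr, _["nct"] = nct,
                      _["n_batches"] = nbatch, _["n_per_batch"] = n_per);
}

// ---------- ray tracing exports ----------
// [[Rcpp::export]]
List trace_ray_cpp(NumericVector p, NumericVector d, List scene) {
  Scene sc = make_scene(scene);
  V3 pos = v3(p[0], p[1], p[2]), dir = v3(d[0], d[1], d[2]);
  if (!sc.inside_world(pos))
    return List::create(_["distance"] = NA_REAL, _["material"] = 3);
  double t = boundary_distance(sc, pos, dir);
  if (t >= INF) return List::create(_["distance"] = NA_REAL, _["material"] = 3);
  int mat = sc.material_at(add(pos, scl(dir, t + EPS)));
  return List::create(_["distance"] = t, _["material"] = mat);
}

// fine-step marching oracle: membership tests only (independent of the
// analytic intersection code above)
// [[Rcpp::export]]
List trace_march_cpp(NumericVector p, NumericVector d, List scene, double step) {
  Scene sc = make_scene(scene);
  V3 pos = v3(p[0], p[1], p[2]), dir = v3(d[0], d[1], d[2]);
  int m0 = sc.material_at(pos);
  double t = 0.0, tmax = 4.0 * sc.world_half;
  while (t < tmax) {
    t += step;
    V3 q = add(pos, scl(dir, t));
    int m = sc.material_at(q);
    if (m != m0) {
      // bisect to refine the crossing
      double a = t - step, b = t;
      for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (a + b);
        if (sc.material_at(add(pos, scl(dir, mid))) == m0) a = mid; else b = mid;
        if (b - a < 1e-9) break;
      }
      int mat = sc.material_at(add(pos, scl(dir, b + EPS)));
      return List::create(_["distance"] = 0.5 * (a + b), _["material"] = mat);
    }
  }
  return List::create(_["distance"] = NA_REAL, _["material"] = 3);
}

// ---------- Klein-Nishina exports ----------
// [[Rcpp::export]]
NumericVector kn_sigma_cpp(NumericVector E) {
  NumericVector out(E.size());
  for (int i = 0; i < E.size(); ++i) out[i] = kn_sigma(E[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix kn_sample_cpp(int n, double E, double seed) {
  Rng g;
  g.seed((uint64_t)seed);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double Eo, ct;
    kn_sample(E, g, Eo, ct);
    out(i, 0) = Eo;
    out(i, 1) = ct;
  }
  colnames(out) = CharacterVector::create("energy", "cos_theta");
  return out;
}

// [[Rcpp::export]]
IntegerVector spectrum_sample_cpp(int n, NumericMatrix spm, double seed) {
  Rng g;
  g.seed((uint64_t)seed);
  int nl = spm.nrow();
  std::vector<double> En(nl), cum(nl);
  double acc = 0;
  for (int i = 0; i < nl; ++i) { acc += spm(i, 1); En[i] = spm(i, 0); cum[i] = acc; }
  for (int i = 0; i < nl; ++i) cum[i] /= acc;
  IntegerVector idx(n);
  for (int k = 0; k < n; ++k) {
    double u = g.u();
    int lo = 0, hi = nl - 1;
    if (u <= cum[0]) { idx[k] = 1; continue; }
    while (hi - lo > 1) { int mid = (lo + hi) / 2; (cum[mid] < u ? lo : hi) = mid; }
    idx[k] = hi + 1;
  }
  return idx;
}

// ---------- kernel superposition onto a 3-D dose grid ----------
// K is (n_r x n_ct), rows indexed by log-r nodes, cols by ascending cos(theta)
// nodes; interpolation is bilinear in (log r, cos theta) of log K.
// [[Rcpp::export]]
NumericVector kernel_grid_cpp(NumericVector logr, NumericVector costh,
                              NumericMatrix K, NumericMatrix centers,
                              NumericMatrix axes, NumericVector weights,
                              int n_axis, double spacing) {
  int nr = logr.size(), nc = costh.size(), ndw = centers.nrow();
  std::vector<double> lk(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) lk[i + nr * j] = std::log(K(i, j));
  NumericVector grid((R_xlen_t)n_axis * n_axis * n_axis);
  double half = (n_axis - 1) / 2.0;
  for (int i = 0; i < ndw; ++i) {
    if (weights[i] == 0) continue;
    double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    double ax = axes(i, 0), ay = axes(i, 1), az = axes(i, 2);
    double w = weights[i];
    R_xlen_t idx = 0;
    for (int kz = 0; kz < n_axis; ++kz) {
      double z = (kz - half) * spacing - cz;
      for (int ky = 0; ky < n_axis; ++ky) {
        double y = (ky - half) * spacing - cy;
        for (int kx = 0; kx < n_axis; ++kx, ++idx) {
          double x = (kx - half) * spacing - cx;
          double r2 = x * x + y * y + z * z;
          double r = std::sqrt(r2);
          double lr = std::log(std::max(r, 1e-6));
          double ct = r > 1e-12 ? (x * ax + y * ay + z * az) / r : 0.0;
          if (lr < logr[0]) lr = logr[0];
          if (lr > logr[nr - 1]) lr = logr[nr - 1];
          if (ct < costh[0]) ct = costh[0];
          if (ct > costh[nc - 1]) ct = costh[nc - 1];
          int ir = nr - 2, ic = nc - 2;
          {
            int lo = 0, hi = nr - 1;
            while (hi - lo > 1) { int mid = (lo + hi) / 2; (logr[mid] <= lr ? lo : hi) = mid; }
            ir = lo;
          }
          {
            int lo = 0, hi = nc - 1;
            while (hi - lo > 1) { int mid = (lo + hi) / 2; (costh[mid] <= ct ? lo : hi) = mid; }
            ic = lo;
          }
          double fr = (lr - logr[ir]) / (logr[ir + 1] - logr[ir]);
          double fc = (ct - costh[ic]) / (costh[ic + 1] - costh[ic]);
          double v00 = lk[ir + nr * ic], v10 = lk[ir + 1 + nr * ic];
          double v01 = lk[ir + nr * (ic + 1)], v11 = lk[ir + 1 + nr * (ic + 1)];
          double lv = v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
                      v01 * (1 - fr) * fc + v11 * fr * fc;
          grid[idx] += w * std::exp(lv);
        }
      }
    }
  }
  return grid;
}
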