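// Analog photon-transport kernel: PCG32 streams, axis-aligned box geometry,
// log-log attenuation lookup, Klein-Nishina / Thomson sampling, kerma tallies.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double MEC2_KEV = 510.99895;
static const double GEOM_EPS = 1e-9;   // cm, post-crossing nudge
// candidate faces must lie strictly ahead but may be far closer than the
// nudge (features thinner than GEOM_EPS would otherwise become invisible)
static const double FACE_TOL = 1e-12;

// ---------------------------------------------------------------------------
// PCG32, one independent stream per history (seeded from master seed + index)
// ---------------------------------------------------------------------------
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t stream) {
    state = 0u; inc = (stream << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((~rot + 1u) & 31));
  }
  // uniform in (0, 1]: never 0, so -log(u) is finite
  double runif_pos() { return (next() + 1.0) * (1.0 / 4294967296.0); }
  // uniform in [0, 1)
  double runif() { return next() * (1.0 / 4294967296.0); }
};

static uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static Pcg32 history_rng(uint64_t master_seed, uint64_t history) {
  uint64_t s = splitmix64(master_seed ^ splitmix64(history));
  return Pcg32(s, splitmix64(s + history));
}

// ---------------------------------------------------------------------------
// Attenuation tables: shared log-energy grid, per-element log components.
// Materials mix element components after per-element log-log interpolation
// (identical to the R-level mu_rho()).
// ---------------------------------------------------------------------------
struct XsTables {
  std::vector<double> logE;                       // n_e
  int n_e, n_elem, n_mat;
  // [elem][component][grid] with component 0=pe, 1=incoherent, 2=coherent
  std::vector<std::vector<std::vector<double>>> logxs;
  std::vector<std::vector<double>> wfrac;         // [mat][elem] weight fractions
  std::vector<double> density;                    // [mat] g/cm3

  int bracket(double le) const {
    int lo = 0, hi = n_e - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; (logE[mid] <= le ? lo : hi) = mid; }
    return lo;
  }
  // linear attenuation components (cm^-1) for material m at energy keV
  void mu_components(int m, double energy, double out[3]) const {
    double le = std::log(energy);
    if (le < logE.front()) le = logE.front();
    if (le > logE.back())  le = logE.back();
    int i = bracket(le);
    double t = (le - logE[i]) / (logE[i + 1] - logE[i]);
    out[0] = out[1] = out[2] = 0.0;
    const std::vector<double>& w = wfrac[m];
    for (int e = 0; e < n_elem; ++e) {
      if (w[e] <= 0.0) continue;
      for (int c = 0; c < 3; ++c) {
        double v = std::exp(logxs[e][c][i] * (1.0 - t) + logxs[e][c][i + 1] * t);
        out[c] += w[e] * v;
      }
    }
    for (int c = 0; c < 3; ++c) out[c] *= density[m];
  }
};

static XsTables make_tables(const List& xs) {
  XsTables tb;
  NumericVector logE = xs["log_energy"];
  tb.logE = std::vector<double>(logE.begin(), logE.end());
  tb.n_e = (int)tb.logE.size();
  List elems = xs["log_components"];   // list per element of 3 x n_e matrix
  tb.n_elem = elems.size();
  tb.logxs.resize(tb.n_elem);
  for (int e = 0; e < tb.n_elem; ++e) {
    NumericMatrix m = elems[e];        // rows: pe, inc, coh
    tb.logxs[e].assign(3, std::vector<double>(tb.n_e));
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < tb.n_e; ++i) tb.logxs[e][c][i] = m(c, i);
  }
  NumericMatrix wf = xs["wfrac"];      // n_mat x n_elem
  NumericVector dens = xs["density"];
  tb.n_mat = wf.nrow();
  tb.wfrac.resize(tb.n_mat);
  for (int m = 0; m < tb.n_mat; ++m)
    tb.wfrac[m] = std::vector<double>(wf(m, _).begin(), wf(m, _).end());
  tb.density = std::vector<double>(dens.begin(), dens.end());
  return tb;
}

// ---------------------------------------------------------------------------
// Geometry: axis-aligned boxes, half-open [min, max) containment, priority
// overlap resolution; points on a face resolve along the travel direction
// via a fixed post-crossing nudge.
// ---------------------------------------------------------------------------
struct SceneCpp {
  int n_box;
  std::vector<double> lo[3], hi[3];
  std::vector<int> cell;      // tally-cell index per box (0-based)
  std::vector<int> mat;       // material index per box
  std::vector<int> prio;
  double wlo[3], whi[3];
  int wcell, wmat;            // world tally cell and material

  bool in_box(int b, const double p[3]) const {
    for (int a = 0; a < 3; ++a)
      if (p[a] < lo[a][b] || p[a] >= hi[a][b]) return false;
    return true;
  }
  bool in_world(const double p[3]) const {
    for (int a = 0; a < 3; ++a)
      if (p[a] < wlo[a] || p[a] >= whi[a]) return false;
    return true;
  }
  // highest-priority box containing p, or -1 for the world region
  int locate(const double p[3]) const {
    int best = -1, bestp = INT_MIN;
    for (int b = 0; b < n_box; ++b)
      if (in_box(b, p) && prio[b] > bestp) { best = b; bestp = prio[b]; }
    return best;
  }
  // distance to the nearest box/world face ahead (classic surface stepping)
  double next_surface(const double p[3], const double u[3], bool& world_exit) const {
    double tmin = std::numeric_limits<double>::infinity();
    double tworld = std::numeric_limits<double>::infinity();
    for (int a = 0; a < 3; ++a) {
      if (u[a] == 0.0) continue;
      double t1 = (wlo[a] - p[a]) / u[a], t2 = (whi[a] - p[a]) / u[a];
      double tx = std::max(t1, t2);
      if (tx < tworld) tworld = tx;
    }
    for (int b = 0; b < n_box; ++b) {
      for (int a = 0; a < 3; ++a) {
        if (u[a] == 0.0) continue;
        double t1 = (lo[a][b] - p[a]) / u[a];
        double t2 = (hi[a][b] - p[a]) / u[a];
        if (t1 > FACE_TOL && t1 < tmin) {
          // candidate plane must actually intersect the box face
          double q[3] = {p[0] + t1 * u[0], p[1] + t1 * u[1], p[2] + t1 * u[2]};
          bool on = true;
          for (int o = 0; o < 3; ++o)
            if (o != a && (q[o] < lo[o][b] - 1e-12 || q[o] > hi[o][b] + 1e-12)) on = false;
          if (on) tmin = t1;
        }
        if (t2 > FACE_TOL && t2 < tmin) {
          double q[3] = {p[0] + t2 * u[0], p[1] + t2 * u[1], p[2] + t2 * u[2]};
          bool on = true;
          for (int o = 0; o < 3; ++o)
            if (o != a && (q[o] < lo[o][b] - 1e-12 || q[o] > hi[o][b] + 1e-12)) on = false;
          if (on) tmin = t2;
        }
      }
    }
    if (tworld <= tmin + GEOM_EPS || !std::isfinite(tmin)) {
      world_exit = true;
      return tworld;
    }
    world_exit = false;
    return tmin;
  }
  // exact exit distance from box b along u (>= 0); the photon is inside b,
  // so the crossing point is always on a face of b. Complements
  // next_surface, whose FACE_TOL can hide an exit face closer than the
  // post-crossing nudge when a box is thinner than GEOM_EPS.
  double exit_box(int b, const double p[3], const double u[3]) const {
    double tmin = std::numeric_limits<double>::infinity();
    for (int a = 0; a < 3; ++a) {
      if (u[a] > 0.0) { double t = (hi[a][b] - p[a]) / u[a]; if (t < tmin) tmin = t; }
      else if (u[a] < 0.0) { double t = (lo[a][b] - p[a]) / u[a]; if (t < tmin) tmin = t; }
    }
    return tmin < 0.0 ? 0.0 : tmin;
  }
};

static SceneCpp make_scene(const List& sc) {
  SceneCpp s;
  NumericMatrix b = sc["bounds"];          // n x 6: xmin xmax ymin ymax zmin zmax
  IntegerVector cell = sc["cell"], mat = sc["mat"], prio = sc["priority"];
  NumericVector wb = sc["world_bounds"];
  s.n_box = b.nrow();
  for (int a = 0; a < 3; ++a) {
    s.lo[a].resize(s.n_box); s.hi[a].resize(s.n_box);
    s.wlo[a] = wb[2 * a]; s.whi[a] = wb[2 * a + 1];
  }
  for (int i = 0; i < s.n_box; ++i) {
    for (int a = 0; a < 3; ++a) { s.lo[a][i] = b(i, 2 * a); s.hi[a][i] = b(i, 2 * a + 1); }
    }
  s.cell = std::vector<int>(cell.begin(), cell.end());
  s.mat  = std::vector<int>(mat.begin(), mat.end());
  s.prio = std::vector<int>(prio.begin(), prio.end());
  s.wcell = as<int>(sc["world_cell"]);
  s.wmat  = as<int>(sc["world_mat"]);
  return s;
}

// ---------------------------------------------------------------------------
// Physics sampling
// ---------------------------------------------------------------------------

// Kahn rejection sampling of the free-electron Klein-Nishina polar angle.
// Returns cos(theta); E'/E follows from the Compton relation.
static double sample_kn_costheta(double energy_keV, Pcg32& rng) {
  double a = energy_keV / MEC2_KEV;
  for (;;) {
    double r1 = rng.runif(), r2 = rng.runif(), r3 = rng.runif();
    if (r1 * (9.0 + 2.0 * a) <= (1.0 + 2.0 * a)) {
      double x = 1.0 + 2.0 * a * r2;                 // x = E/E'
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return 1.0 - (x - 1.0) / a;
    } else {
      double x = (1.0 + 2.0 * a) / (1.0 + 2.0 * a * r2);
      double ct = 1.0 - (x - 1.0) / a;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return ct;
    }
  }
}

// Thomson angular law (1 + cos^2)/2 by rejection
static double sample_thomson_costheta(Pcg32& rng) {
  for (;;) {
    double ct = 2.0 * rng.runif() - 1.0;
    if (rng.runif() <= 0.5 * (1.0 + ct * ct)) return ct;
  }
}

// Rotate unit vector u by polar angle (ct = cos theta) and azimuth phi in the
// local frame; degenerate pole |u_z| ~ 1 handled with an x-axis based frame.
static void rotate_direction(double u[3], double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  double nx, ny, nz;
  if (std::fabs(uz) < 0.99999) {
    double s = std::sqrt(ux * ux + uy * uy);
    nx = ux * ct + st * (ux * uz * cp - uy * sp) / s;
    ny = uy * ct + st * (uy * uz * cp + ux * sp) / s;
    nz = uz * ct - s * st * cp;
  } else {
    // frame built from the x axis; uz = +-1
    nx = st * cp;
    ny = st * sp;
    nz = uz * ct;
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  u[0] = nx / norm; u[1] = ny / norm; u[2] = nz / norm;
}

static void isotropic_direction(double u[3], Pcg32& rng) {
  double ct = 2.0 * rng.runif() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.runif();
  u[0] = st * std::cos(phi); u[1] = st * std::sin(phi); u[2] = ct;
}

// ---------------------------------------------------------------------------
// Source
// ---------------------------------------------------------------------------
struct SourceCpp {
  int kind;                  // 0 isotropic point, 1 collimated pyramid
  double pos[3];
  double energy;
  double fx0, fx1, fy0, fy1, fz;  // footprint rectangle on plane z = fz
  double axis[3], cos_max;        // bounding cone for the footprint
};

static SourceCpp make_source(const List& src) {
  SourceCpp s;
  s.kind = as<int>(src["kind"]);
  NumericVector p = src["position"];
  for (int a = 0; a < 3; ++a) s.pos[a] = p[a];
  s.energy = as<double>(src["energy"]);
  if (s.kind == 1) {
    NumericVector f = src["footprint"];  // xmin xmax ymin ymax z
    s.fx0 = f[0]; s.fx1 = f[1]; s.fy0 = f[2]; s.fy1 = f[3]; s.fz = f[4];
    double cx = 0.5 * (s.fx0 + s.fx1), cy = 0.5 * (s.fy0 + s.fy1);
    double ax = cx - s.pos[0], ay = cy - s.pos[1], az = s.fz - s.pos[2];
    double n = std::sqrt(ax * ax + ay * ay + az * az);
    s.axis[0] = ax / n; s.axis[1] = ay / n; s.axis[2] = az / n;
    s.cos_max = 1.0;
    double xs[2] = {s.fx0, s.fx1}, ys[2] = {s.fy0, s.fy1};
    for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) {
      double dx = xs[i] - s.pos[0], dy = ys[j] - s.pos[1], dz = s.fz - s.pos[2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double c = (dx * s.axis[0] + dy * s.axis[1] + dz * s.axis[2]) / d;
      if (c < s.cos_max) s.cos_max = c;
    }
  } else {
    s.fx0 = s.fx1 = s.fy0 = s.fy1 = s.fz = 0.0;
    s.axis[0] = s.axis[1] = 0.0; s.axis[2] = -1.0; s.cos_max = -1.0;
  }
  return s;
}

// emit one photon; direction uniform on the sphere (isotropic) or uniform
// over the solid angle subtended by the footprint (collimated, by cone
// rejection against the footprint rectangle)
static void emit_one(const SourceCpp& s, Pcg32& rng, double p[3], double u[3]) {
  for (int a = 0; a < 3; ++a) p[a] = s.pos[a];
  if (s.kind == 0) {
    isotropic_direction(u, rng);
    return;
  }
  for (;;) {
    double ct = s.cos_max + (1.0 - s.cos_max) * rng.runif();
    double phi = 2.0 * M_PI * rng.runif();
    double v[3] = {s.axis[0], s.axis[1], s.axis[2]};
    rotate_direction(v, ct, phi);
    if (v[2] * (s.fz - s.pos[2]) <= 0.0) continue;   // parallel or wrong way
    double t = (s.fz - s.pos[2]) / v[2];
    double x = s.pos[0] + t * v[0], y = s.pos[1] + t * v[1];
    if (x >= s.fx0 && x <= s.fx1 && y >= s.fy0 && y <= s.fy1) {
      u[0] = v[0]; u[1] = v[1]; u[2] = v[2];
      return;
    }
  }
}

// ---------------------------------------------------------------------------
// Planar crossing tallies
// ---------------------------------------------------------------------------
struct PlaneCpp {
  int axis;                   // 0,1,2
  double coord, lo1, hi1, lo2, hi2;   // bounds on the other two axes (asc. index)
  bool primaries_only;
};

static std::vector<PlaneCpp> make_planes(const List& pl) {
  std::vector<PlaneCpp> out;
  if (pl.size() == 0) return out;
  NumericMatrix m = pl["def"];   // n x 7: axis coord lo1 hi1 lo2 hi2 primaries
  for (int i = 0; i < m.nrow(); ++i) {
    PlaneCpp p;
    p.axis = (int)m(i, 0); p.coord = m(i, 1);
    p.lo1 = m(i, 2); p.hi1 = m(i, 3); p.lo2 = m(i, 4); p.hi2 = m(i, 5);
    p.primaries_only = m(i, 6) != 0.0;
    out.push_back(p);
  }
  return out;
}

static void score_planes(const std::vector<PlaneCpp>& planes,
                         std::vector<double>& counts,
                         const double p0[3], const double p1[3],
                         bool primary, double weight) {
  for (size_t i = 0; i < planes.size(); ++i) {
    const PlaneCpp& pl = planes[i];
    if (pl.primaries_only && !primary) continue;
    double a0 = p0[pl.axis], a1 = p1[pl.axis];
    if ((a0 - pl.coord) * (a1 - pl.coord) >= 0.0) continue;   // no strict crossing
    double t = (pl.coord - a0) / (a1 - a0);
    int o1 = (pl.axis == 0) ? 1 : 0;
    int o2 = (pl.axis == 2) ? 1 : 2;
    double q1 = p0[o1] + t * (p1[o1] - p0[o1]);
    double q2 = p0[o2] + t * (p1[o2] - p0[o2]);
    if (q1 >= pl.lo1 && q1 <= pl.hi1 && q2 >= pl.lo2 && q2 <= pl.hi2)
      counts[i] += weight;
  }
}

// ---------------------------------------------------------------------------
// Batch runner
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_batch(List scene, List xs, List source, List planes,
                   double cutoff_keV, bool coherent_enabled,
                   int max_interactions, double n_histories, double seed) {
  SceneCpp sc = make_scene(scene);
  XsTables tb = make_tables(xs);
  SourceCpp so = make_source(source);
  std::vector<PlaneCpp> pls = make_planes(planes);

  int n_cells = 0;
  for (int b = 0; b < sc.n_box; ++b) n_cells = std::max(n_cells, sc.cell[b] + 1);
  n_cells = std::max(n_cells, sc.wcell + 1);

  std::vector<double> dep_sum(n_cells, 0.0), dep_sumsq(n_cells, 0.0);
  std::vector<double> hist_dep(n_cells, 0.0);
  std::vector<double> plane_counts(pls.size(), 0.0);
  double emitted = 0.0, deposited = 0.0, escaped = 0.0;
  double max_cons_err = 0.0;
  double n_aborted = 0.0, n_zero_interaction = 0.0;
  uint64_t ms = (uint64_t)seed;
  int64_t nh = (int64_t)n_histories;

  for (int64_t h = 0; h < nh; ++h) {
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    Pcg32 rng = history_rng(ms, (uint64_t)h);
    double p[3], u[3];
    emit_one(so, rng, p, u);
    double E = so.energy, w = 1.0;
    emitted += E * w;
    std::fill(hist_dep.begin(), hist_dep.end(), 0.0);
    double esc = 0.0;
    int n_int = 0;
    bool alive = sc.in_world(p);
    if (!alive) esc = E;    // emitted outside the world box: immediate escape

    while (alive) {
      int row = sc.locate(p);
      int mat = (row < 0) ? sc.wmat : sc.mat[row];
      int cell = (row < 0) ? sc.wcell : sc.cell[row];
      double mu[3] = {0.0, 0.0, 0.0};
      double mu_tot = 0.0;
      if (mat >= 0) {       // mat < 0 encodes vacuum
        tb.mu_components(mat, E, mu);
        if (!coherent_enabled) mu[2] = 0.0;
        mu_tot = mu[0] + mu[1] + mu[2];
      }
      bool world_exit = false;
      double d_surf = sc.next_surface(p, u, world_exit);
      if (row >= 0) {
        double e = sc.exit_box(row, p, u);
        if (e < d_surf) { d_surf = e; world_exit = false; }
      }
      double s = (mu_tot > 1e-12)
        ? -std::log(rng.runif_pos()) / mu_tot
        : std::numeric_limits<double>::infinity();

      if (s < d_surf) {
        double p1[3] = {p[0] + s * u[0], p[1] + s * u[1], p[2] + s * u[2]};
        score_planes(pls, plane_counts, p, p1, n_int == 0, w);
        p[0] = p1[0]; p[1] = p1[1]; p[2] = p1[2];
        double r = rng.runif() * mu_tot;
        if (r < mu[0]) {                       // photoelectric: full local deposit
          hist_dep[cell] += E * w;
          alive = false;
        } else if (r < mu[0] + mu[1]) {        // incoherent (Compton)
          double ct = sample_kn_costheta(E, rng);
          double Ep = E / (1.0 + (E / MEC2_KEV) * (1.0 - ct));
          hist_dep[cell] += (E - Ep) * w;      // kerma approximation
          E = Ep;
          rotate_direction(u, ct, 2.0 * M_PI * rng.runif());
          ++n_int;
          if (E < cutoff_keV) { hist_dep[cell] += E * w; alive = false; }
        } else {                               // coherent: elastic deflection
          double ct = sample_thomson_costheta(rng);
          rotate_direction(u, ct, 2.0 * M_PI * rng.runif());
          ++n_int;
        }
        if (alive && n_int >= max_interactions) {
          hist_dep[cell] += E * w;             // deposit remainder, terminate
          alive = false;
          n_aborted += 1.0;
        }
      } else {
        double d = d_surf + GEOM_EPS;
        double p1[3] = {p[0] + d * u[0], p[1] + d * u[1], p[2] + d * u[2]};
        score_planes(pls, plane_counts, p, p1, n_int == 0, w);
        p[0] = p1[0]; p[1] = p1[1]; p[2] = p1[2];
        if (world_exit || !sc.in_world(p)) {
          esc = E * w;
          alive = false;
        }
      }
    }

    if (n_int == 0 && esc > 0.0) n_zero_interaction += 1.0;
    double tot = esc;
    for (int c = 0; c < n_cells; ++c) {
      tot += hist_dep[c];
      dep_sum[c] += hist_dep[c];
      dep_sumsq[c] += hist_dep[c] * hist_dep[c];
      deposited += hist_dep[c];
    }
    escaped += esc;
    double err = std::fabs(tot - so.energy * w);
    if (err > max_cons_err) max_cons_err = err;
  }

  return List::create(
    _["dep_sum"] = NumericVector(dep_sum.begin(), dep_sum.end()),
    _["dep_sumsq"] = NumericVector(dep_sumsq.begin(), dep_sumsq.end()),
    _["plane_counts"] = NumericVector(plane_counts.begin(), plane_counts.end()),
    _["n_histories"] = (double)nh,
    _["emitted_keV"] = emitted,
    _["deposited_keV"] = deposited,
    _["escaped_keV"] = escaped,
    _["max_conservation_err_keV"] = max_cons_err,
    _["n_aborted"] = n_aborted,
    _["n_zero_interaction_escapes"] = n_zero_interaction);
}

// ---------------------------------------------------------------------------
// Exported primitives (same kernels as the batch runner) for testing and
// direct use from R
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_locate(List scene, NumericMatrix points) {
  SceneCpp sc = make_scene(scene);
  int n = points.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    if (!sc.in_world(p)) { out[i] = NA_INTEGER; continue; }
    int row = sc.locate(p);
    out[i] = row < 0 ? 0 : row + 1;        // 1-based row, 0 = world
  }
  return out;
}

// [[Rcpp::export]]
List cpp_distance_to_boundary(List scene, NumericVector point, NumericVector dir) {
  SceneCpp sc = make_scene(scene);
  double p[3] = {point[0], point[1], point[2]};
  double u[3] = {dir[0], dir[1], dir[2]};
  if (!sc.in_world(p)) stop("point is outside the world region");
  int cur = sc.locate(p);
  double total = 0.0;
  for (int guard = 0; guard < 100000; ++guard) {
    bool world_exit = false;
    double d = sc.next_surface(p, u, world_exit);
    int here = sc.locate(p);
    if (here >= 0) {
      double e = sc.exit_box(here, p, u);
      if (e < d) { d = e; world_exit = false; }
    }
    total += d;
    double q[3] = {p[0] + (d + GEOM_EPS) * u[0], p[1] + (d + GEOM_EPS) * u[1],
                   p[2] + (d + GEOM_EPS) * u[2]};
    if (world_exit || !sc.in_world(q)) {
      return List::create(_["distance"] = total, _["next_row"] = NA_INTEGER,
                          _["escaped"] = true);
    }
    int nxt = sc.locate(q);
    if (nxt != cur) {
      return List::create(_["distance"] = total,
                          _["next_row"] = (nxt < 0 ? 0 : nxt + 1),
                          _["escaped"] = false);
    }
    p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
  }
  stop("no region change found (corrupt scene?)");
}

// [[Rcpp::export]]
NumericVector cpp_sample_free_path(double n, double mu, double seed) {
  int64_t nn = (int64_t)n;
  NumericVector out(nn);
  for (int64_t i = 0; i < nn; ++i) {
    Pcg32 rng = history_rng((uint64_t)seed, (uint64_t)i);
    out[i] = -std::log(rng.runif_pos()) / mu;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double n, double energy_keV, double seed) {
  int64_t nn = (int64_t)n;
  NumericMatrix out(nn, 3);   // energy_keV, theta, phi
  for (int64_t i = 0; i < nn; ++i) {
    Pcg32 rng = history_rng((uint64_t)seed, (uint64_t)i);
    double ct = sample_kn_costheta(energy_keV, rng);
    out(i, 0) = energy_keV / (1.0 + (energy_keV / MEC2_KEV) * (1.0 - ct));
    out(i, 1) = std::acos(std::min(1.0, std::max(-1.0, ct)));
    out(i, 2) = 2.0 * M_PI * rng.runif();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_coherent(double n, double seed) {
  int64_t nn = (int64_t)n;
  NumericMatrix out(nn, 2);   // theta, phi
  for (int64_t i = 0; i < nn; ++i) {
    Pcg32 rng = history_rng((uint64_t)seed, (uint64_t)i);
    out(i, 0) = std::acos(std::min(1.0, std::max(-1.0, sample_thomson_costheta(rng))));
    out(i, 1) = 2.0 * M_PI * rng.runif();
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_channel(double n, NumericVector partials, double seed) {
  int64_t nn = (int64_t)n;
  double tot = partials[0] + partials[1] + partials[2];
  if (tot <= 0) stop("all partial coefficients are zero");
  IntegerVector out(nn);
  for (int64_t i = 0; i < nn; ++i) {
    Pcg32 rng = history_rng((uint64_t)seed, (uint64_t)i);
    double r = rng.runif() * tot;
    out[i] = (r < partials[0]) ? 1 : (r < partials[0] + partials[1] ? 2 : 3);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_emit(List source, double n, double seed) {
  SourceCpp so = make_source(source);
  int64_t nn = (int64_t)n;
  NumericMatrix out(nn, 7);
  for (int64_t i = 0; i < nn; ++i) {
    Pcg32 rng = history_rng((uint64_t)seed, (uint64_t)i);
    double p[3], u[3];
    emit_one(so, rng, p, u);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
    out(i, 3) = u[0]; out(i, 4) = u[1]; out(i, 5) = u[2];
    out(i, 6) = so.energy;
  }
  return out;
}
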