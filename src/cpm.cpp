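// Cellular Potts engine: lattice energetics, Metropolis-Hastings dynamics,
// cell geometry/contact queries and the coupled physical+decision run loop.
//
// Conventions shared with the R layer:
//   * grid is an integer matrix, grid[x, y] (1-based in R); value 0 = medium,
//     n > 0 = cell identifier.  The outermost one-site ring is an immutable
//     medium frame: flip proposals never pick a frame site as source.
//   * cell types: 1 = A, 2 = B; sigma index for contact energies:
//     0 = medium, 1 = A, 2 = B.  J is a 3x3 symmetric matrix in that order.
//   * phases: 1 = G1, 2 = SG2M, 3 = APOPTOTIC.
//   * rng state: 12 doubles = three xoroshiro128++ streams (lattice,
//     decision, cycle), each stored as 4 x 32-bit halves.  Keeping the
//     streams separate means decision-rule changes do not perturb the
//     lattice trajectory for a given seed.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ----------------------------------------------------------------- RNG ----

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Stream {
  uint64_t s0, s1;
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = rotl64(a + b, 17) + a;
    b ^= a;
    s0 = rotl64(a, 49) ^ b ^ (b << 21);
    s1 = rotl64(b, 28);
    return r;
  }
  inline double unif() {              // [0, 1)
    return (next() >> 11) * 1.1102230246251565e-16;
  }
  inline int below(int n) {           // uniform in {0, ..., n-1}
    return (int)(((uint64_t)(uint32_t)(next() >> 32) * (uint64_t)n) >> 32);
  }
  inline double gauss(double mu, double sd) {
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    return mu + sd * std::sqrt(-2.0 * std::log(u1)) *
                     std::cos(6.283185307179586 * u2);
  }
  // truncated-below Gaussian (resample; hard clamp as last resort)
  inline double gauss_trunc(double mu, double sd, double lo) {
    double x = gauss(mu, sd);
    int guard = 0;
    while (x < lo && ++guard < 1024) x = gauss(mu, sd);
    return x < lo ? lo : x;
  }
};

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
NumericVector cpp_rng_init(double seed) {
  NumericVector out(12);
  for (int s = 0; s < 3; ++s) {
    uint64_t x = (uint64_t)seed * 0x9E3779B97F4A7C15ULL +
                 (uint64_t)(s + 1) * 0xD1B54A32D192ED03ULL;
    uint64_t a = splitmix64(x), b = splitmix64(x);
    if (!(a | b)) a = 0x9E3779B9ULL;
    out[4 * s + 0] = (double)(a >> 32);
    out[4 * s + 1] = (double)(a & 0xFFFFFFFFULL);
    out[4 * s + 2] = (double)(b >> 32);
    out[4 * s + 3] = (double)(b & 0xFFFFFFFFULL);
  }
  return out;
}

static Stream load_stream(const NumericVector &st, int s) {
  Stream r;
  r.s0 = ((uint64_t)st[4 * s + 0] << 32) | (uint64_t)st[4 * s + 1];
  r.s1 = ((uint64_t)st[4 * s + 2] << 32) | (uint64_t)st[4 * s + 3];
  return r;
}

static void store_stream(NumericVector &st, int s, const Stream &r) {
  st[4 * s + 0] = (double)(r.s0 >> 32);
  st[4 * s + 1] = (double)(r.s0 & 0xFFFFFFFFULL);
  st[4 * s + 2] = (double)(r.s1 >> 32);
  st[4 * s + 3] = (double)(r.s1 & 0xFFFFFFFFULL);
}

// stream indices
enum { STR_LATTICE = 0, STR_DECISION = 1, STR_CYCLE = 2 };

// [[Rcpp::export]]
List cpp_runif_stream(int n, NumericVector rng, int stream) {
  Stream r = load_stream(rng, stream);
  NumericVector x(n);
  for (int i = 0; i < n; ++i) x[i] = r.unif();
  NumericVector out = clone(rng);
  store_stream(out, stream, r);
  return List::create(_["x"] = x, _["rng"] = out);
}

// [[Rcpp::export]]
List cpp_rnorm_stream(int n, double mu, double sd, double lo,
                      NumericVector rng, int stream) {
  Stream r = load_stream(rng, stream);
  NumericVector x(n);
  for (int i = 0; i < n; ++i) x[i] = r.gauss_trunc(mu, sd, lo);
  NumericVector out = clone(rng);
  store_stream(out, stream, r);
  return List::create(_["x"] = x, _["rng"] = out);
}

// ------------------------------------------------------------- offsets ----

// full neighbourhood: first 4 von Neumann, all 8 Moore
static const int DX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int DY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
// half offsets (each unordered pair visited once)
static const int HX8[4] = {1, 0, 1, 1};
static const int HY8[4] = {0, 1, 1, -1};

// ---------------------------------------------------------------- world ----

struct TypePars {
  double lam, G, k;
  double sizer_mean, sizer_sd, timer_mean, timer_sd;
  double p_den_max, rho_half, beta;
  double p_con_max, S, hill_n;
};

struct World {
  int W, H, nn;        // grid dims (frame included), neighbourhood order 4|8
  double kT;
  double apo_floor;    // apoptotic removal floor (sites)
  double con_epoch;    // steps per fitted contact-hazard epoch
  std::vector<int> grid;
  int next_id;
  // registry, indexed by id; index 0 unused (medium)
  std::vector<int> type, label, phase, gen;
  std::vector<char> alive;
  std::vector<int> area;
  std::vector<double> tgt, sizer, timer;
  TypePars tp[3];
  double J[3][3];
  Stream rl, rd, rc;
  inline int sig(int id) const { return id ? type[id] : 0; }
  inline int at(int x, int y) const { return grid[x + y * (size_t)W]; }
  void ensure(int id) {
    if (id < (int)type.size()) return;
    size_t n = id + 1;
    type.resize(n, 0); label.resize(n, 0); phase.resize(n, 1);
    gen.resize(n, 0); alive.resize(n, 0); area.resize(n, 0);
    tgt.resize(n, 0.0); sizer.resize(n, 0.0); timer.resize(n, 0.0);
  }
};

static TypePars read_tp(List p) {
  TypePars t;
  t.lam = as<double>(p["lam"]);
  t.G = as<double>(p["G"]);
  t.k = as<double>(p["k"]);
  t.sizer_mean = as<double>(p["sizer_mean"]);
  t.sizer_sd = as<double>(p["sizer_sd"]);
  t.timer_mean = as<double>(p["timer_mean"]);
  t.timer_sd = as<double>(p["timer_sd"]);
  t.p_den_max = as<double>(p["p_den_max"]);
  t.rho_half = as<double>(p["rho_half"]);
  t.beta = as<double>(p["beta"]);
  t.p_con_max = as<double>(p["p_con_max"]);
  t.S = as<double>(p["S"]);
  t.hill_n = as<double>(p["hill_n"]);
  return t;
}

// cells: list of parallel vectors id, type, label, area, target_area,
// phase, sizer, timer, generation (all numeric/integer, types coded 1/2)
static World make_world(IntegerMatrix grid, List cells, List pars,
                        NumericVector rng) {
  World w;
  w.W = grid.nrow();
  w.H = grid.ncol();
  w.grid.assign(grid.begin(), grid.end());
  IntegerVector id = cells["id"], ty = cells["type"], lb = cells["label"],
                ph = cells["phase"], gn = cells["generation"],
                ar = cells["area"];
  NumericVector tg = cells["target_area"], sz = cells["sizer"],
                tm = cells["timer"];
  int mx = 0;
  for (int i = 0; i < id.size(); ++i) mx = std::max(mx, id[i]);
  int nid = as<int>(pars["next_id"]);
  w.next_id = std::max(nid, mx + 1);
  w.ensure(std::max(mx, 1));
  for (int i = 0; i < id.size(); ++i) {
    int c = id[i];
    if (c <= 0) stop("cell ids must be positive");
    w.type[c] = ty[i]; w.label[c] = lb[i]; w.phase[c] = ph[i];
    w.gen[c] = gn[i]; w.area[c] = ar[i]; w.tgt[c] = tg[i];
    w.sizer[c] = sz[i]; w.timer[c] = tm[i]; w.alive[c] = 1;
  }
  w.tp[1] = read_tp(pars["A"]);
  w.tp[2] = read_tp(pars["B"]);
  NumericMatrix J = pars["J"];
  if (J.nrow() != 3 || J.ncol() != 3) stop("J must be 3x3 (M, A, B)");
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) w.J[i][j] = J(i, j);
  w.kT = as<double>(pars["kT"]);
  if (!(w.kT > 0)) stop("kT must be > 0");
  w.nn = as<int>(pars["nneigh"]);
  if (w.nn != 4 && w.nn != 8) stop("neighbourhood order must be 4 or 8");
  w.apo_floor = as<double>(pars["apo_floor"]);
  w.con_epoch = pars.containsElementNamed("contact_epoch")
                    ? as<double>(pars["contact_epoch"]) : 1.0;
  if (!(w.con_epoch >= 1.0)) stop("contact_epoch must be >= 1");
  w.rl = load_stream(rng, STR_LATTICE);
  w.rd = load_stream(rng, STR_DECISION);
  w.rc = load_stream(rng, STR_CYCLE);
  // every nonzero grid id must be registered
  for (size_t i = 0; i < w.grid.size(); ++i) {
    int g = w.grid[i];
    if (g < 0) stop("negative identifier on grid");
    if (g > 0 && (g >= (int)w.alive.size() || !w.alive[g]))
      stop("grid identifier missing from registry");
  }
  return w;
}

static List world_cells(const World &w) {
  std::vector<int> keep;
  for (int c = 1; c < (int)w.alive.size(); ++c)
    if (w.alive[c]) keep.push_back(c);
  int n = keep.size();
  IntegerVector id(n), ty(n), lb(n), ph(n), gn(n), ar(n);
  NumericVector tg(n), sz(n), tm(n);
  for (int i = 0; i < n; ++i) {
    int c = keep[i];
    id[i] = c; ty[i] = w.type[c]; lb[i] = w.label[c]; ph[i] = w.phase[c];
    gn[i] = w.gen[c]; ar[i] = w.area[c]; tg[i] = w.tgt[c];
    sz[i] = w.sizer[c]; tm[i] = w.timer[c];
  }
  return List::create(_["id"] = id, _["type"] = ty, _["label"] = lb,
                      _["area"] = ar, _["target_area"] = tg,
                      _["phase"] = ph, _["sizer"] = sz, _["timer"] = tm,
                      _["generation"] = gn);
}

// --------------------------------------------------------------- energy ----

static double contact_energy(const World &w) {
  double E = 0.0;
  int nh = (w.nn == 8) ? 4 : 2;
  for (int y = 0; y < w.H; ++y) {
    for (int x = 0; x < w.W; ++x) {
      int a = w.at(x, y);
      for (int k = 0; k < nh; ++k) {
        int nx = x + HX8[k], ny = y + HY8[k];
        if (nx < 0 || nx >= w.W || ny < 0 || ny >= w.H) continue;
        int b = w.at(nx, ny);
        if (a != b) E += w.J[w.sig(a)][w.sig(b)];
      }
    }
  }
  return E;
}

static double elastic_energy(const World &w) {
  double E = 0.0;
  for (int c = 1; c < (int)w.alive.size(); ++c) {
    if (!w.alive[c]) continue;
    double d = (double)w.area[c] - w.tgt[c];
    E += w.tp[w.type[c]].lam * d * d;
  }
  return E;
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix grid, List cells, List pars) {
  World w = make_world(grid, cells, pars, NumericVector(12));
  return contact_energy(w) + elastic_energy(w);
}

// local energy change for flipping site (x, y) [0-based] to identity cand
static double local_dE(const World &w, int x, int y, int b) {
  int a = w.at(x, y);
  if (a == b) return 0.0;
  int sa = w.sig(a), sb = w.sig(b);
  double dE = 0.0;
  for (int k = 0; k < w.nn; ++k) {
    int nx = x + DX8[k], ny = y + DY8[k];
    if (nx < 0 || nx >= w.W || ny < 0 || ny >= w.H) continue;
    int n = w.at(nx, ny);
    int sn = w.sig(n);
    if (n != a) dE -= w.J[sa][sn];
    if (n != b) dE += w.J[sb][sn];
  }
  if (a) {
    double d = (double)w.area[a] - w.tgt[a];
    dE += w.tp[w.type[a]].lam * ((d - 1.0) * (d - 1.0) - d * d);
  }
  if (b) {
    double d = (double)w.area[b] - w.tgt[b];
    dE += w.tp[w.type[b]].lam * ((d + 1.0) * (d + 1.0) - d * d);
  }
  return dE;
}

// [[Rcpp::export]]
double cpp_delta_energy(IntegerMatrix grid, List cells, List pars,
                        int x, int y, int cand) {
  World w = make_world(grid, cells, pars, NumericVector(12));
  if (x < 2 || x > w.W - 1 || y < 2 || y > w.H - 1)
    stop("site lies on the immutable boundary frame");
  return local_dE(w, x - 1, y - 1, cand);
}

// ------------------------------------------------------------- dynamics ----

static void mcs_once(World &w, long attempts) {
  int Wi = w.W - 2, Hi = w.H - 2;  // interior extents
  for (long t = 0; t < attempts; ++t) {
    int x = 1 + w.rl.below(Wi);
    int y = 1 + w.rl.below(Hi);
    int a = w.at(x, y);
    int cand[8];
    int nc = 0;
    for (int k = 0; k < w.nn; ++k) {
      int n = w.at(x + DX8[k], y + DY8[k]);
      if (n == a) continue;
      bool seen = false;
      for (int i = 0; i < nc; ++i)
        if (cand[i] == n) { seen = true; break; }
      if (!seen) cand[nc++] = n;
    }
    if (nc == 0) continue;  // attempt consumed without a valid proposal
    int b = (nc == 1) ? cand[0] : cand[w.rl.below(nc)];
    double dE = local_dE(w, x, y, b);
    bool acc = (dE <= 0.0) || (w.rl.unif() < std::exp(-dE / w.kT));
    if (acc) {
      w.grid[x + y * (size_t)w.W] = b;
      if (a) w.area[a] -= 1;
      if (b) w.area[b] += 1;
    }
  }
}

// ---------------------------------------------------------- contact scan ----

struct Scan {
  std::vector<int> tot, het, hom, med;  // boundary contact counts per id
  std::vector<double> rho;              // local density per id
  std::vector<uint64_t> pairs;          // scratch: cell-cell contact keys
};

static void scan_contacts(const World &w, Scan &s) {
  size_t cap = w.alive.size();
  s.tot.assign(cap, 0); s.het.assign(cap, 0);
  s.hom.assign(cap, 0); s.med.assign(cap, 0);
  s.rho.assign(cap, 0.0);
  s.pairs.clear();
  int nh = (w.nn == 8) ? 4 : 2;
  for (int y = 0; y < w.H; ++y) {
    for (int x = 0; x < w.W; ++x) {
      int a = w.at(x, y);
      for (int k = 0; k < nh; ++k) {
        int nx = x + HX8[k], ny = y + HY8[k];
        if (nx < 0 || nx >= w.W || ny < 0 || ny >= w.H) continue;
        int b = w.at(nx, ny);
        if (a == b) continue;
        if (a) {
          s.tot[a]++;
          if (!b) s.med[a]++;
          else if (w.type[b] == w.type[a]) s.hom[a]++;
          else s.het[a]++;
        }
        if (b) {
          s.tot[b]++;
          if (!a) s.med[b]++;
          else if (w.type[a] == w.type[b]) s.hom[b]++;
          else s.het[b]++;
        }
        if (a && b) {
          uint64_t u = std::min(a, b), v = std::max(a, b);
          s.pairs.push_back((u << 32) | v);
        }
      }
    }
  }
  std::sort(s.pairs.begin(), s.pairs.end());
  s.pairs.erase(std::unique(s.pairs.begin(), s.pairs.end()),
                s.pairs.end());
  for (uint64_t key : s.pairs) {
    int u = (int)(key >> 32), v = (int)(key & 0xFFFFFFFFULL);
    if (w.area[v] > 0) s.rho[u] += 1.0 / (double)w.area[v];
    if (w.area[u] > 0) s.rho[v] += 1.0 / (double)w.area[u];
  }
  for (size_t c = 1; c < cap; ++c)
    if (w.alive[c] && w.area[c] > 0) s.rho[c] += 1.0 / (double)w.area[c];
}

// [[Rcpp::export]]
List cpp_contact_scan(IntegerMatrix grid, List cells, List pars) {
  World w = make_world(grid, cells, pars, NumericVector(12));
  Scan s;
  scan_contacts(w, s);
  std::vector<int> keep;
  for (int c = 1; c < (int)w.alive.size(); ++c)
    if (w.alive[c]) keep.push_back(c);
  int n = keep.size();
  IntegerVector id(n), tot(n), het(n), hom(n), med(n);
  NumericVector rho(n), pab(n);
  for (int i = 0; i < n; ++i) {
    int c = keep[i];
    id[i] = c; tot[i] = s.tot[c]; het[i] = s.het[c];
    hom[i] = s.hom[c]; med[i] = s.med[c]; rho[i] = s.rho[c];
    pab[i] = s.tot[c] > 0 ? (double)s.het[c] / (double)s.tot[c] : 0.0;
  }
  return List::create(_["id"] = id, _["total"] = tot, _["hetero"] = het,
                      _["homo"] = hom, _["medium"] = med,
                      _["p_ab"] = pab, _["rho"] = rho);
}

// ------------------------------------------------------------- geometry ----

// centroid, second-moment (population covariance) and principal axis of a
// cell's site set; ties in the eigen problem break toward the first axis
static void geometry_of(const std::vector<int> &xs, const std::vector<int> &ys,
                        double out[8]) {
  int n = xs.size();
  double cx = 0, cy = 0;
  for (int i = 0; i < n; ++i) { cx += xs[i]; cy += ys[i]; }
  cx /= n; cy /= n;
  double sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = xs[i] - cx, dy = ys[i] - cy;
    sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
  }
  sxx /= n; syy /= n; sxy /= n;
  double ux, uy;
  if (std::fabs(sxy) < 1e-12) {
    if (sxx >= syy) { ux = 1.0; uy = 0.0; } else { ux = 0.0; uy = 1.0; }
  } else {
    double half = 0.5 * (sxx + syy);
    double disc = std::sqrt(0.25 * (sxx - syy) * (sxx - syy) + sxy * sxy);
    double l1 = half + disc;
    ux = l1 - syy; uy = sxy;
    double nm = std::sqrt(ux * ux + uy * uy);
    ux /= nm; uy /= nm;
  }
  out[0] = cx; out[1] = cy; out[2] = sxx; out[3] = syy; out[4] = sxy;
  out[5] = ux; out[6] = uy; out[7] = (double)n;
}

// [[Rcpp::export]]
List cpp_cell_geometry(IntegerMatrix grid, int id) {
  int W = grid.nrow(), H = grid.ncol();
  std::vector<int> xs, ys;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (grid(x, y) == id) { xs.push_back(x + 1); ys.push_back(y + 1); }
  if (xs.empty()) stop("no sites carry identifier %d", id);
  double g[8];
  geometry_of(xs, ys, g);
  return List::create(
      _["centroid"] = NumericVector::create(g[0], g[1]),
      _["cov"] = NumericMatrix(2, 2,
          NumericVector::create(g[2], g[4], g[4], g[3]).begin()),
      _["axis"] = NumericVector::create(g[5], g[6]),
      _["area"] = (int)g[7]);
}

// ------------------------------------------------------------- division ----

// split the mother's sites by projection onto the principal axis; the first
// half (most negative projections) goes to d1.  Deterministic ordering.
static bool divide_one(World &w, int id, int &d1, int &d2) {
  std::vector<int> xs, ys;
  size_t npix = w.grid.size();
  for (size_t i = 0; i < npix; ++i) {
    if (w.grid[i] == id) {
      xs.push_back((int)(i % w.W));
      ys.push_back((int)(i / w.W));
    }
  }
  int n = xs.size();
  if (n < 2) return false;
  double g[8];
  geometry_of(xs, ys, g);
  double ux = g[5], uy = g[6], cx = g[0] - 1, cy = g[1] - 1;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::vector<double> proj(n);
  for (int i = 0; i < n; ++i)
    proj[i] = (xs[i] - cx) * ux + (ys[i] - cy) * uy;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (proj[i] != proj[j]) return proj[i] < proj[j];
    if (xs[i] != xs[j]) return xs[i] < xs[j];
    return ys[i] < ys[j];
  });
  d1 = w.next_id++;
  d2 = w.next_id++;
  w.ensure(d2);
  int half = n / 2;
  for (int i = 0; i < n; ++i) {
    int s = ord[i];
    w.grid[xs[s] + ys[s] * (size_t)w.W] = (i < half) ? d1 : d2;
  }
  const TypePars &p = w.tp[w.type[id]];
  int dd[2] = {d1, d2};
  int sizes[2] = {half, n - half};
  for (int q = 0; q < 2; ++q) {
    int c = dd[q];
    w.type[c] = w.type[id];
    w.label[c] = w.label[id];
    w.area[c] = sizes[q];
    w.tgt[c] = (double)sizes[q];      // mechanical equilibrium at birth
    w.phase[c] = 1;
    w.gen[c] = w.gen[id] + 1;
    w.sizer[c] = w.rc.gauss_trunc(p.sizer_mean, p.sizer_sd, 1.0);
    w.timer[c] = w.rc.gauss_trunc(p.timer_mean, p.timer_sd, 1.0);
    w.alive[c] = 1;
  }
  w.alive[id] = 0;
  w.area[id] = 0;
  return true;
}

// [[Rcpp::export]]
List cpp_divide(IntegerMatrix grid, List cells, List pars,
                NumericVector rng, int id) {
  World w = make_world(grid, cells, pars, rng);
  if (id <= 0 || id >= (int)w.alive.size() || !w.alive[id])
    stop("unknown or dead cell id %d", id);
  int d1 = 0, d2 = 0;
  bool ok = divide_one(w, id, d1, d2);
  NumericVector rng_out = clone(rng);
  store_stream(rng_out, STR_CYCLE, w.rc);
  IntegerMatrix gout(w.W, w.H);
  std::copy(w.grid.begin(), w.grid.end(), gout.begin());
  return List::create(_["ok"] = ok, _["grid"] = gout,
                      _["cells"] = world_cells(w),
                      _["daughters"] = IntegerVector::create(d1, d2),
                      _["next_id"] = w.next_id, _["rng"] = rng_out);
}

// -------------------------------------------------------- fragmentation ----

// connected components per live identifier (diagnostic: the dynamics impose
// no connectivity constraint, so fragmentation is monitored, not forbidden)
// [[Rcpp::export]]
DataFrame cpp_components(IntegerMatrix grid, int nneigh) {
  int W = grid.nrow(), H = grid.ncol();
  int nn = (nneigh == 8) ? 8 : 4;
  std::vector<char> seen((size_t)W * H, 0);
  std::unordered_map<int, int> comp;
  std::vector<int> stack;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      size_t i0 = x + y * (size_t)W;
      int id = grid[i0];
      if (id == 0 || seen[i0]) continue;
      comp[id]++;
      stack.clear();
      stack.push_back((int)i0);
      seen[i0] = 1;
      while (!stack.empty()) {
        int i = stack.back();
        stack.pop_back();
        int cx = i % W, cy = i / W;
        for (int k = 0; k < nn; ++k) {
          int nx = cx + DX8[k], ny = cy + DY8[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          size_t j = nx + ny * (size_t)W;
          if (!seen[j] && grid[j] == id) {
            seen[j] = 1;
            stack.push_back((int)j);
          }
        }
      }
    }
  }
  std::vector<int> ids, counts;
  for (auto &kv : comp) { ids.push_back(kv.first); counts.push_back(kv.second); }
  return DataFrame::create(_["id"] = ids, _["components"] = counts);
}

// ------------------------------------------------------------- run loop ----

static inline double hill_p(double pab, const TypePars &p) {
  if (pab <= 0.0) return 0.0;
  double num = std::pow(pab, p.hill_n);
  return p.p_con_max * num / (std::pow(p.S, p.hill_n) + num);
}

// One full coupled step: Monte-Carlo sweep, then (optionally) the decision
// layer: growth, cycle/division, apoptosis hazards, extrusion/removal.
// Metrics row layout (by *label*, so pseudo-clones are tracked):
//   step nA nB rhoA rhoB divA divB adenA adenB aconA aconB
//   extrA extrB remA remB
#define NMET 15

// [[Rcpp::export]]
List cpp_run(IntegerMatrix grid, List cells, List pars, NumericVector rng,
             int steps, double attempts, bool decisions,
             bool stop_on_extinction, int step0) {
  World w = make_world(grid, cells, pars, rng);
  long att = (long)attempts;
  if (att <= 0) att = (long)w.W * (long)w.H;
  std::vector<double> met;
  met.reserve((size_t)steps * NMET);
  int steps_done = 0;
  bool extinct = false;
  Scan s;
  std::vector<int> dividers;
  std::unordered_set<int> kill;

  for (int t = 0; t < steps; ++t) {
    mcs_once(w, att);
    double ev[10] = {0};  // divA divB adenA adenB aconA aconB extrA extrB remA remB
    if (decisions) {
      // growth + cycle (over ids existing at the start of this step)
      int cap0 = (int)w.alive.size();
      dividers.clear();
      for (int c = 1; c < cap0; ++c) {
        if (!w.alive[c] || w.phase[c] == 3) continue;
        const TypePars &p = w.tp[w.type[c]];
        double d = (double)w.area[c] - w.tgt[c];
        if (d <= 0.0) w.tgt[c] += p.G * std::exp(-p.k * d * d);
        if (w.phase[c] == 1) {
          if ((double)w.area[c] >= w.sizer[c]) w.phase[c] = 2;
        } else {
          w.timer[c] -= 1.0;
          if (w.timer[c] <= 0.0) dividers.push_back(c);
        }
      }
      for (int c : dividers) {
        if (w.area[c] < 2) continue;  // deferred until the cell has 2 sites
        int d1, d2;
        if (divide_one(w, c, d1, d2)) ev[0 + (w.label[d1] - 1)] += 1;
      }
      // hazards need fresh contact structure (post-division)
      scan_contacts(w, s);
      int cap = (int)w.alive.size();
      for (int c = 1; c < cap; ++c) {
        if (!w.alive[c] || w.phase[c] == 3) continue;
        double u1 = w.rd.unif(), u2 = w.rd.unif();
        const TypePars &p = w.tp[w.type[c]];
        double pden = p.p_den_max /
                      (1.0 + std::exp(-p.beta * (s.rho[c] - p.rho_half)));
        double pab = s.tot[c] > 0 ? (double)s.het[c] / (double)s.tot[c] : 0.0;
        // fitted curve gives a per-epoch probability; fold to per-step hazard
        double pcon = hill_p(pab, p);
        if (w.con_epoch > 1.0)
          pcon = 1.0 - std::pow(1.0 - pcon, 1.0 / w.con_epoch);
        if (u1 < pden) {
          w.phase[c] = 3; w.tgt[c] = 0.0;
          ev[2 + (w.label[c] - 1)] += 1;
        } else if (u2 < pcon) {
          w.phase[c] = 3; w.tgt[c] = 0.0;
          ev[4 + (w.label[c] - 1)] += 1;
        }
      }
      // extrusion (strict < mean/4) and apoptotic removal
      double sumA[3] = {0, 0, 0};
      int cnt[3] = {0, 0, 0};
      for (int c = 1; c < cap; ++c) {
        if (!w.alive[c]) continue;
        sumA[w.type[c]] += w.area[c];
        cnt[w.type[c]]++;
      }
      double mean[3] = {0, 0, 0};
      for (int q = 1; q < 3; ++q) if (cnt[q]) mean[q] = sumA[q] / cnt[q];
      kill.clear();
      for (int c = 1; c < cap; ++c) {
        if (!w.alive[c]) continue;
        bool extr = cnt[w.type[c]] > 1 &&
                    (double)w.area[c] < mean[w.type[c]] / 4.0;
        bool apo_gone = w.phase[c] == 3 && (double)w.area[c] < w.apo_floor;
        bool empty = w.area[c] <= 0;
        if (extr || apo_gone || empty) {
          kill.insert(c);
          if (extr && w.phase[c] != 3) ev[6 + (w.label[c] - 1)] += 1;
          ev[8 + (w.label[c] - 1)] += 1;
        }
      }
      if (!kill.empty()) {
        for (size_t i = 0; i < w.grid.size(); ++i)
          if (w.grid[i] && kill.count(w.grid[i])) w.grid[i] = 0;
        for (int c : kill) { w.alive[c] = 0; w.area[c] = 0; }
      }
    }
    // record metrics (counts/density by label over live cells)
    double nA = 0, nB = 0, rA = 0, rB = 0;
    int rnA = 0, rnB = 0;
    int cap = (int)w.alive.size();
    for (int c = 1; c < cap; ++c) {
      if (!w.alive[c]) continue;
      if (w.label[c] == 1) nA++; else nB++;
      if (decisions && w.phase[c] != 3) {
        if (w.label[c] == 1) { rA += s.rho[c]; rnA++; }
        else { rB += s.rho[c]; rnB++; }
      }
    }
    met.push_back(step0 + t + 1);
    met.push_back(nA); met.push_back(nB);
    met.push_back(rnA ? rA / rnA : NA_REAL);
    met.push_back(rnB ? rB / rnB : NA_REAL);
    for (int q = 0; q < 10; ++q) met.push_back(ev[q]);
    steps_done = t + 1;
    if (stop_on_extinction && (nA == 0 || nB == 0)) {
      extinct = true;
      break;
    }
  }

  NumericVector rng_out(12);
  store_stream(rng_out, STR_LATTICE, w.rl);
  store_stream(rng_out, STR_DECISION, w.rd);
  store_stream(rng_out, STR_CYCLE, w.rc);
  IntegerMatrix gout(w.W, w.H);
  std::copy(w.grid.begin(), w.grid.end(), gout.begin());
  int nrow = met.size() / NMET;
  NumericMatrix mout(nrow, NMET);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < NMET; ++j) mout(i, j) = met[(size_t)i * NMET + j];
  return List::create(_["grid"] = gout, _["cells"] = world_cells(w),
                      _["metrics"] = mout, _["rng"] = rng_out,
                      _["next_id"] = w.next_id,
                      _["steps_done"] = steps_done,
                      _["extinct"] = extinct);
}

// ---------------------------------------------------------- tessellation ----

// nearest-centre tessellation of the interior (frame stays medium);
// ties break toward the lower centre index
// [[Rcpp::export]]
IntegerMatrix cpp_voronoi(int W, int H, NumericVector cx, NumericVector cy) {
  IntegerMatrix grid(W, H);
  int n = cx.size();
  if (n < 1) stop("need at least one centre");
  for (int y = 1; y < H - 1; ++y) {
    for (int x = 1; x < W - 1; ++x) {
      double best = 1e300;
      int bi = 0;
      double px = x + 1, py = y + 1;  // 1-based site coordinates
      for (int i = 0; i < n; ++i) {
        double dx = px - cx[i], dy = py - cy[i];
        double d = dx * dx + dy * dy;
        if (d < best - 1e-12) { best = d; bi = i; }
      }
      grid(x, y) = bi + 1;
    }
  }
  return grid;
}
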