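// Spatial single-cell birth-death core on a 3D Moore-neighborhood lattice.
// Exact Gillespie scheme: per-cell birth rate lambda0 * multiplier * psi,
// psi = (empty Moore neighbors)/26. By default the death rate is also
// density-modulated (mu * psi), so the embedded per-cell process along
// active lineages is an exact lambda:mu branching process (extinction
// probability rho, total births ~ N/(1-rho)) and the tumor interior is
// quiescent and dense — the regime the divergence analysis assumes. The
// uniform-death variant (rate mu per alive cell regardless of density) is
// available via density_dep_death = false.
// Birth/death cell selection uses rejection sampling bounded by 26 * maxMult
// (resp. 26), exact because every per-cell rate is below the bound; running
// rate sums are rebuilt exactly every 2^16 events to cancel fp drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double draw_s_one(double s_mean, double s_sd) {
  if (s_mean <= 0.0) return 0.0;
  if (s_sd <= 0.0) return s_mean;
  double v;
  do { v = R::rnorm(s_mean, s_sd); } while (v < 0.0);
  return v;
}

// Gaussian(s_mean, s_sd) truncated at zero by resampling.
// [[Rcpp::export]]
NumericVector cpp_draw_selection(int n, double s_mean, double s_sd) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_s_one(s_mean, s_sd);
  return out;
}

// Variant gains for one daughter birth: Bernoulli(u) passenger (or Poisson(u)
// behind the flag) and an independent Bernoulli(ub) driver with truncated
// Gaussian selection coefficient. Returns kinds (0 passenger / 1 driver),
// coordinates and s values; multiplier factor = prod(1+s) over new drivers.
// [[Rcpp::export]]
List cpp_birth_mutations(double u, double ub, double s_mean, double s_sd,
                         bool poisson_mut, double glen_pass, double glen_driver) {
  std::vector<int> kind;
  std::vector<double> coord, sval;
  int n_pass = poisson_mut ? (int)R::rpois(u) : (unif_rand() < u ? 1 : 0);
  for (int j = 0; j < n_pass; ++j) {
    kind.push_back(0);
    coord.push_back(1.0 + std::floor(unif_rand() * glen_pass));
    sval.push_back(0.0);
  }
  double mult_factor = 1.0;
  if (unif_rand() < ub) {
    double s = draw_s_one(s_mean, s_sd);
    kind.push_back(1);
    coord.push_back(1.0 + std::floor(unif_rand() * glen_driver));
    sval.push_back(s);
    mult_factor *= (1.0 + s);
  }
  return List::create(_["kind"] = wrap(kind), _["coordinate"] = wrap(coord),
                      _["s_value"] = wrap(sval), _["mult_factor"] = mult_factor);
}

struct Registry {
  std::vector<int> parent;          // 0 for founder
  std::vector<int16_t> x, y, z;
  std::vector<double> tb, td;       // td = -1 while alive / disseminated
  std::vector<double> mlt;
  std::vector<uint8_t> dis;
};

// [[Rcpp::export]]
List cpp_grow_tumor(double lambda0, double mu, double u, double ub,
                    double s_mean, double s_sd, bool poisson_mut,
                    double target, double ns,
                    double glen_pass, double glen_driver,
                    double founder_mult, int hist_points,
                    double lattice_factor, bool density_dep_death) {
  if (target < 1) stop("target size must be >= 1");
  if (target > 2e7) stop("target size too large for the in-memory lattice");
  if (lambda0 <= 0) stop("lambda0 must be positive");
  if (mu < 0) stop("mu must be non-negative");

  // margin: ball radius x factor plus absolute padding (the growth front is
  // rough; the relative roughness is worst at small sizes)
  const int margin = (int)std::ceil(std::cbrt(3.0 * target / (4.0 * M_PI)) * lattice_factor) + 16;
  const int S = 2 * margin + 1;
  const long long S2 = (long long)S * S, S3 = S2 * S;
  std::vector<int32_t> grid((size_t)S3, 0);

  long long off[26];
  int noff = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) off[noff++] = dx + (long long)S * dy + S2 * dz;

  Registry reg;
  size_t cap = (size_t)std::min(4.0 * target + 1024.0, 4.2e7);
  reg.parent.reserve(cap); reg.x.reserve(cap); reg.y.reserve(cap);
  reg.z.reserve(cap); reg.tb.reserve(cap); reg.td.reserve(cap);
  reg.mlt.reserve(cap); reg.dis.reserve(cap);

  std::vector<int> psi;       // empty Moore neighbors, valid while alive
  std::vector<long long> pos; // packed lattice index, -1 if off-lattice
  std::vector<int> aliveIdx;  // position in `alive`, -1 if not alive
  std::vector<int> alive;     // cell ids
  psi.reserve(cap); pos.reserve(cap); aliveIdx.reserve(cap);

  std::vector<int>    var_kind, var_origin;
  std::vector<double> var_coord, var_s, var_t;
  std::vector<int>    seed_idx, seed_cell;
  std::vector<double> seed_size, seed_t;
  std::vector<double> hist_t, hist_n;

  const double c26 = lambda0 / 26.0;
  double sumB = 0.0, maxMult = founder_mult;
  long long sumPsi = 0; // exact running sum of empty-neighbor counts

  auto decode = [&](long long p, int &xx, int &yy, int &zz) {
    xx = (int)(p % S); long long r = p / S; yy = (int)(r % S); zz = (int)(r / S);
  };

  auto new_cell = [&](int parent, long long p, double t, double m, uint8_t d) -> int {
    int xx, yy, zz; decode(p, xx, yy, zz);
    if (xx <= 0 || yy <= 0 || zz <= 0 || xx >= S - 1 || yy >= S - 1 || zz >= S - 1)
      stop("tumor reached the lattice boundary");
    reg.parent.push_back(parent);
    reg.x.push_back((int16_t)(xx - margin));
    reg.y.push_back((int16_t)(yy - margin));
    reg.z.push_back((int16_t)(zz - margin));
    reg.tb.push_back(t); reg.td.push_back(-1.0);
    reg.mlt.push_back(m); reg.dis.push_back(d);
    psi.push_back(0); pos.push_back(-1); aliveIdx.push_back(-1);
    return (int)reg.parent.size(); // 1-based id
  };

  // place cell id at p: update neighbors' psi and sumB, compute own psi
  auto place = [&](int id, long long p) {
    int cnt = 0;
    for (int k = 0; k < 26; ++k) {
      long long q = p + off[k];
      int32_t j = grid[(size_t)q];
      if (j) { psi[j - 1]--; sumPsi--; sumB -= c26 * reg.mlt[j - 1]; }
      else cnt++;
    }
    grid[(size_t)p] = id;
    pos[id - 1] = p;
    psi[id - 1] = cnt;
    sumPsi += cnt;
    sumB += c26 * reg.mlt[id - 1] * cnt;
    aliveIdx[id - 1] = (int)alive.size();
    alive.push_back(id);
  };

  auto unplace = [&](int id) { // death or removal: vacate the site
    long long p = pos[id - 1];
    grid[(size_t)p] = 0;
    sumB -= c26 * reg.mlt[id - 1] * psi[id - 1];
    sumPsi -= psi[id - 1];
    for (int k = 0; k < 26; ++k) {
      long long q = p + off[k];
      int32_t j = grid[(size_t)q];
      if (j) { psi[j - 1]++; sumPsi++; sumB += c26 * reg.mlt[j - 1]; }
    }
    pos[id - 1] = -1;
    int ai = aliveIdx[id - 1], last = alive.back();
    alive[ai] = last; aliveIdx[last - 1] = ai;
    alive.pop_back(); aliveIdx[id - 1] = -1;
  };

  auto rebuild = [&]() {
    double s = 0.0;
    for (int id : alive) s += c26 * reg.mlt[id - 1] * psi[id - 1];
    sumB = s;
  };

  // founder at lattice center, time zero
  {
    long long pc = margin + (long long)S * margin + S2 * margin;
    int fid = new_cell(0, pc, 0.0, founder_mult, 0);
    place(fid, pc);
  }

  double t = 0.0;
  long long nextI = 1;
  bool pending = false, extinct = false;
  long long n_birth_events = 0, n_death_events = 0, evt = 0;
  const long long hstep = std::max((long long)1, (long long)(target / std::max(hist_points, 1)));
  long long maxN = 1;
  hist_t.push_back(0.0); hist_n.push_back(1.0);

  // keep going until a pending seeding fires, so reaching I*ns == target
  // still yields its seeding event (floor(target/ns) events in total)
  while ((double)alive.size() < target || pending) {
    if (alive.empty()) { extinct = true; break; }
    double sumD = density_dep_death ? mu * (double)sumPsi / 26.0
                                    : mu * (double)alive.size();
    double Rtot = sumB + sumD;
    if (Rtot <= 0) stop("no active cells left on the lattice");
    t += R::exp_rand() / Rtot;
    bool is_birth = (unif_rand() * Rtot < sumB);
    if (is_birth) {
      // rejection selection proportional to mlt * psi
      int i = 0;
      long tries = 0;
      for (;;) {
        i = alive[(size_t)(unif_rand() * alive.size())];
        if (unif_rand() * (26.0 * maxMult) < reg.mlt[i - 1] * (double)psi[i - 1]) break;
        if (++tries == 50000000L) { rebuild(); if (sumB <= 0) stop("no cell can divide"); }
      }
      // uniformly chosen empty Moore neighbor
      long long p = pos[i - 1];
      long long empties[26]; int ne = 0;
      for (int k = 0; k < 26; ++k) {
        long long q = p + off[k];
        if (!grid[(size_t)q]) empties[ne++] = q;
      }
      long long q = empties[(int)(unif_rand() * ne)];
      // daughter genotype
      double m2 = reg.mlt[i - 1];
      int n_pass = poisson_mut ? (int)R::rpois(u) : (unif_rand() < u ? 1 : 0);
      bool has_driver = (unif_rand() < ub);
      double sdrv = has_driver ? draw_s_one(s_mean, s_sd) : 0.0;
      if (has_driver) m2 *= (1.0 + sdrv);
      uint8_t d = pending ? 1 : 0;
      int id2 = new_cell(i, q, t, m2, d);
      for (int j = 0; j < n_pass; ++j) {
        var_kind.push_back(0);
        var_coord.push_back(1.0 + std::floor(unif_rand() * glen_pass));
        var_s.push_back(0.0); var_origin.push_back(id2); var_t.push_back(t);
      }
      if (has_driver) {
        var_kind.push_back(1);
        var_coord.push_back(1.0 + std::floor(unif_rand() * glen_driver));
        var_s.push_back(sdrv); var_origin.push_back(id2); var_t.push_back(t);
      }
      if (m2 > maxMult) maxMult = m2;
      if (pending) {
        // the next-born cell disseminates: never joins the primary lattice
        seed_idx.push_back((int)nextI);
        seed_cell.push_back(id2);
        seed_size.push_back((double)alive.size());
        seed_t.push_back(t);
        pending = false;
        nextI++;
      } else {
        place(id2, q);
        if (ns > 0 && (double)alive.size() >= (double)nextI * ns) pending = true;
        if ((long long)alive.size() > maxN && (long long)alive.size() % hstep == 0) {
          maxN = (long long)alive.size();
          hist_t.push_back(t); hist_n.push_back((double)maxN);
        }
      }
      n_birth_events++;
    } else {
      int i;
      if (density_dep_death) {
        for (;;) { // death rate proportional to psi: rejection on psi/26
          i = alive[(size_t)(unif_rand() * alive.size())];
          if (unif_rand() * 26.0 < (double)psi[i - 1]) break;
        }
      } else {
        i = alive[(size_t)(unif_rand() * alive.size())];
      }
      unplace(i);
      reg.td[i - 1] = t;
      n_death_events++;
    }
    if ((++evt & 0xFFFFLL) == 0) { rebuild(); Rcpp::checkUserInterrupt(); }
  }

  // assemble registry
  size_t n = reg.parent.size();
  IntegerVector cid(n), par(n), cx(n), cy(n), cz(n);
  NumericVector tb(n), td(n), ml(n);
  IntegerVector ds(n);
  for (size_t i = 0; i < n; ++i) {
    cid[i] = (int)i + 1; par[i] = reg.parent[i];
    cx[i] = reg.x[i]; cy[i] = reg.y[i]; cz[i] = reg.z[i];
    tb[i] = reg.tb[i];
    td[i] = reg.td[i] < 0 ? NA_REAL : reg.td[i];
    ml[i] = reg.mlt[i]; ds[i] = reg.dis[i];
  }
  par.attr("class") = R_NilValue;
  size_t nv = var_kind.size();
  IntegerVector vid(nv);
  for (size_t i = 0; i < nv; ++i) vid[i] = (int)i + 1;

  IntegerVector alive_ids(alive.size());
  for (size_t i = 0; i < alive.size(); ++i) alive_ids[i] = alive[i];

  return List::create(
    _["cells"] = DataFrame::create(
      _["cell_id"] = cid, _["parent_id"] = par,
      _["x"] = cx, _["y"] = cy, _["z"] = cz,
      _["t_birth"] = tb, _["t_death"] = td,
      _["disseminated"] = ds, _["multiplier"] = ml),
    _["variants"] = DataFrame::create(
      _["variant_id"] = vid, _["coordinate"] = wrap(var_coord),
      _["kind"] = wrap(var_kind), _["s_value"] = wrap(var_s),
      _["origin_cell"] = wrap(var_origin), _["t_origin"] = wrap(var_t)),
    _["seeding"] = DataFrame::create(
      _["seed_index"] = wrap(seed_idx), _["seeding_cell"] = wrap(seed_cell),
      _["primary_size_at_seed"] = wrap(seed_size), _["t_seed"] = wrap(seed_t)),
    _["size_history"] = DataFrame::create(
      _["time"] = wrap(hist_t), _["population"] = wrap(hist_n)),
    _["alive_ids"] = alive_ids,
    _["extinct"] = extinct,
    _["final_time"] = t,
    _["n_birth_events"] = (double)n_birth_events,
    _["n_death_events"] = (double)n_death_events);
}

// Observed-descendant counts per cell for one or more observation sets.
// parent is 0 for the founder; ids must satisfy parent[i] < i+1 (birth order).
// observed: n x m logical matrix. counts[i, j] includes cell i itself when
// observed. Accumulates leaf-to-root in one reverse pass.
// [[Rcpp::export]]
IntegerMatrix cpp_descendant_counts(IntegerVector parent, LogicalMatrix observed) {
  int n = parent.size(), m = observed.ncol();
  if (observed.nrow() != n) stop("observed must have one row per cell");
  IntegerMatrix counts(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      counts(i, j) = observed(i, j) ? 1 : 0;
  for (int i = n - 1; i >= 0; --i) {
    int p = parent[i];
    if (p > 0)
      for (int j = 0; j < m; ++j) counts(p - 1, j) += counts(i, j);
  }
  return counts;
}
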