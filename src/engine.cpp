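// Off-lattice tumor-immune ABM engine.
//
// Overdamped pairwise repulsion on a fine time step; persistent-random-walk
// migration, contact-inhibited division, apoptosis and timed one-to-one
// immune attacks on a coarser phenotype step. All randomness comes from R's
// global RNG stream (RNGScope), so a set.seed() in R makes runs exactly
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Domain {
  double xmin, xmax, ymin, ymax;
};

inline double reflect1(double v, double lo, double hi) {
  // fold back into [lo, hi]; displacements are small relative to the domain
  // so this loop runs at most a couple of times
  while (v < lo || v > hi) {
    if (v < lo) v = 2.0 * lo - v;
    if (v > hi) v = 2.0 * hi - v;
  }
  return v;
}

// Deterministic pseudo-random separation axis for exactly coincident pairs,
// keyed on the (ordered) agent ids.
inline double coincident_angle(int id_a, int id_b) {
  int lo = id_a < id_b ? id_a : id_b;
  int hi = id_a < id_b ? id_b : id_a;
  double h = std::sin(lo * 12.9898 + hi * 78.233) * 43758.5453;
  h -= std::floor(h);
  return 2.0 * M_PI * h;
}

// Uniform binning over the rectangular domain. Bin width is at least the
// maximal interaction range, so all interacting pairs sit in adjacent bins.
struct Grid {
  int nx, ny;
  double x0, y0, wx, wy;
  std::vector<std::vector<int>> bins;

  void setup(const Domain& dom, double range) {
    double ex = dom.xmax - dom.xmin, ey = dom.ymax - dom.ymin;
    nx = std::max(1, (int)std::floor(ex / range));
    ny = std::max(1, (int)std::floor(ey / range));
    x0 = dom.xmin; y0 = dom.ymin;
    wx = ex / nx; wy = ey / ny;
    bins.assign((size_t)nx * ny, {});
  }
  inline int bin_of(double x, double y) const {
    int ix = (int)((x - x0) / wx); if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    int iy = (int)((y - y0) / wy); if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    return iy * nx + ix;
  }
  void fill(const std::vector<double>& x, const std::vector<double>& y,
            const std::vector<char>& alive) {
    for (auto& b : bins) b.clear();
    for (size_t i = 0; i < x.size(); ++i) {
      if (alive[i]) bins[bin_of(x[i], y[i])].push_back((int)i);
    }
  }
  template <typename F>
  void for_neighbors(double x, double y, F f) const {
    int ix = (int)((x - x0) / wx); if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    int iy = (int)((y - y0) / wy); if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    for (int by = std::max(0, iy - 1); by <= std::min(ny - 1, iy + 1); ++by) {
      for (int bx = std::max(0, ix - 1); bx <= std::min(nx - 1, ix + 1); ++bx) {
        for (int j : bins[(size_t)by * nx + bx]) f(j);
      }
    }
  }
};

struct Engine {
  // per-agent state (index order == id order; ids strictly increasing)
  std::vector<double> x, y, dirx, diry, timer;
  std::vector<int> id, type, partner;  // partner: agent index or -1
  std::vector<char> alive;
  int next_id = 0;

  // per-type parameters (phenotype-step probabilities / step lengths)
  std::vector<double> div_p, apo_p, step_len, redraw_p, radius;
  std::vector<int> max_nb;

  int attacker_type, target_type;
  double attack_p, attack_duration, kill_prob, contact_scale;
  double repulsion, dt_mech, dt_phen;
  Domain dom;
  double range;  // maximal interaction distance
  Grid grid;

  // epoch counters
  int n_div = 0, n_apo = 0, n_kill = 0, n_started = 0;

  void release_pair(int i) {
    int j = partner[i];
    if (j >= 0) { partner[j] = -1; timer[j] = 0.0; }
    partner[i] = -1;
    timer[i] = 0.0;
  }

  void mechanics_substep() {
    grid.fill(x, y, alive);
    size_t n = x.size();
    std::vector<double> dx(n, 0.0), dy(n, 0.0);
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      grid.for_neighbors(x[i], y[i], [&](int j) {
        if (j <= (int)i) return;
        double R = radius[type[i]] + radius[type[j]];
        double ddx = x[i] - x[j], ddy = y[i] - y[j];
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 >= R * R) return;
        double d = std::sqrt(d2);
        double mag = dt_mech * repulsion;
        double ux, uy;
        if (d < 1e-12) {
          double a = coincident_angle(id[i], id[j]);
          ux = std::cos(a); uy = std::sin(a);
          // full overlap: (1 - d/R)^2 == 1
        } else {
          double f = 1.0 - d / R;
          mag *= f * f;
          ux = ddx / d; uy = ddy / d;
        }
        dx[i] += mag * ux; dy[i] += mag * uy;
        dx[j] -= mag * ux; dy[j] -= mag * uy;
      });
    }
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i] || partner[i] >= 0) continue;  // attack-locked: frozen
      x[i] = reflect1(x[i] + dx[i], dom.xmin, dom.xmax);
      y[i] = reflect1(y[i] + dy[i], dom.ymin, dom.ymax);
    }
  }

  void migration_step() {
    size_t n = x.size();
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i] || partner[i] >= 0) continue;
      int t = type[i];
      if (step_len[t] <= 0.0) continue;
      if (unif_rand() < redraw_p[t]) {
        double a = 2.0 * M_PI * unif_rand();
        dirx[i] = std::cos(a); diry[i] = std::sin(a);
      }
      x[i] = reflect1(x[i] + step_len[t] * dirx[i], dom.xmin, dom.xmax);
      y[i] = reflect1(y[i] + step_len[t] * diry[i], dom.ymin, dom.ymax);
    }
  }

  void division_death_step() {
    grid.fill(x, y, alive);
    size_t n0 = x.size();  // daughters appended this epoch are not processed
    // neighbor counts for contact inhibition, computed before any change
    std::vector<int> nb(n0, 0);
    for (size_t i = 0; i < n0; ++i) {
      if (!alive[i] || div_p[type[i]] <= 0.0) continue;
      int cnt = 0;
      grid.for_neighbors(x[i], y[i], [&](int j) {
        if (j == (int)i) return;
        double thr = contact_scale * (radius[type[i]] + radius[type[j]]);
        double ddx = x[i] - x[j], ddy = y[i] - y[j];
        if (ddx * ddx + ddy * ddy <= thr * thr) ++cnt;
      });
      nb[i] = cnt;
    }
    for (size_t i = 0; i < n0; ++i) {
      if (!alive[i]) continue;
      int t = type[i];
      if (div_p[t] > 0.0) {
        double u = unif_rand();
        if (u < div_p[t] && nb[i] <= max_nb[t]) {
          double a = 2.0 * M_PI * unif_rand();
          double cx = reflect1(x[i] + radius[t] * std::cos(a),
                               dom.xmin, dom.xmax);
          double cy = reflect1(y[i] + radius[t] * std::sin(a),
                               dom.ymin, dom.ymax);
          x.push_back(cx); y.push_back(cy);
          dirx.push_back(1.0); diry.push_back(0.0);
          timer.push_back(0.0);
          id.push_back(next_id++);
          type.push_back(t);
          partner.push_back(-1);
          alive.push_back(1);
          ++n_div;
        }
      }
      if (apo_p[t] > 0.0) {
        double u = unif_rand();
        if (u < apo_p[t]) {
          if (partner[i] >= 0) release_pair(i);  // frees the attacker
          alive[i] = 0;
          ++n_apo;
        }
      }
    }
  }

  void attack_step() {
    grid.fill(x, y, alive);
    size_t n = x.size();
    // (i) free attackers in contact with an untargeted target may engage
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i] || type[i] != attacker_type || partner[i] >= 0) continue;
      int best = -1;
      double best_d2 = 0.0;
      grid.for_neighbors(x[i], y[i], [&](int j) {
        if (j == (int)i || !alive[j] || type[j] != target_type) return;
        if (partner[j] >= 0) return;  // already targeted
        double thr = contact_scale * (radius[type[i]] + radius[type[j]]);
        double ddx = x[i] - x[j], ddy = y[i] - y[j];
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 > thr * thr) return;
        if (best < 0 || d2 < best_d2 ||
            (d2 == best_d2 && id[j] < id[best])) {
          best = j; best_d2 = d2;
        }
      });
      if (best >= 0) {
        double u = unif_rand();
        if (u < attack_p) {
          partner[i] = best;
          partner[best] = (int)i;
          timer[i] = 0.0; timer[best] = 0.0;
          ++n_started;
        }
      }
    }
    // (iii) advance timers; resolve completed attacks
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i] || type[i] != attacker_type || partner[i] < 0) continue;
      timer[i] += dt_phen;
      timer[partner[i]] = timer[i];
      if (timer[i] >= attack_duration - 1e-9) {
        int j = partner[i];
        double u = unif_rand();
        if (u < kill_prob) {
          alive[j] = 0;
          ++n_kill;
        }
        release_pair((int)i);
      }
    }
  }

  void compact() {
    size_t n = x.size();
    std::vector<int> remap(n, -1);
    size_t k = 0;
    for (size_t i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      remap[i] = (int)k;
      if (k != i) {
        x[k] = x[i]; y[k] = y[i]; dirx[k] = dirx[i]; diry[k] = diry[i];
        timer[k] = timer[i]; id[k] = id[i]; type[k] = type[i];
        partner[k] = partner[i]; alive[k] = alive[i];
      }
      ++k;
    }
    x.resize(k); y.resize(k); dirx.resize(k); diry.resize(k);
    timer.resize(k); id.resize(k); type.resize(k); partner.resize(k);
    alive.resize(k);
    for (size_t i = 0; i < k; ++i) {
      if (partner[i] >= 0) partner[i] = remap[partner[i]];
    }
  }

  List snapshot(double t) const {
    size_t n = x.size();
    IntegerVector sid(n), stype(n), spartner(n);
    NumericVector sx(n), sy(n), stimer(n);
    int pairs = 0;
    for (size_t i = 0; i < n; ++i) {
      sid[i] = id[i];
      stype[i] = type[i] + 1;  // 1-based for R
      sx[i] = x[i]; sy[i] = y[i]; stimer[i] = timer[i];
      spartner[i] = partner[i] >= 0 ? id[partner[i]] : NA_INTEGER;
      if (partner[i] >= 0 && type[i] == attacker_type) ++pairs;
    }
    return List::create(_["time"] = t, _["id"] = sid, _["type"] = stype,
                        _["x"] = sx, _["y"] = sy, _["partner"] = spartner,
                        _["timer"] = stimer, _["ongoing_attacks"] = pairs);
  }
};

}  // namespace

// [[Rcpp::export]]
List abm_run_cpp(NumericVector x0, NumericVector y0, IntegerVector type0,
                 NumericVector div_rate_h, NumericVector apo_rate_h,
                 NumericVector speed, NumericVector persistence,
                 NumericVector radius, IntegerVector max_nb,
                 double attack_rate, double attack_duration, double kill_prob,
                 double contact_scale, int attacker_type, int target_type,
                 double repulsion, double dt_mech, double dt_phen,
                 NumericVector domain, double duration,
                 double save_interval) {
  Engine e;
  int n = x0.size();
  int n_types = div_rate_h.size();
  e.dom = {domain[0], domain[1], domain[2], domain[3]};
  double rmax = 0.0;
  for (int t = 0; t < n_types; ++t) rmax = std::max(rmax, radius[t]);
  e.range = std::max(2.0 * rmax, contact_scale * 2.0 * rmax);
  e.grid.setup(e.dom, e.range);

  e.x.assign(x0.begin(), x0.end());
  e.y.assign(y0.begin(), y0.end());
  e.type.resize(n);
  for (int i = 0; i < n; ++i) e.type[i] = type0[i] - 1;  // 0-based
  e.id.resize(n);
  for (int i = 0; i < n; ++i) e.id[i] = i;
  e.next_id = n;
  e.partner.assign(n, -1);
  e.timer.assign(n, 0.0);
  e.alive.assign(n, 1);
  e.dirx.assign(n, 1.0);
  e.diry.assign(n, 0.0);

  e.div_p.resize(n_types); e.apo_p.resize(n_types);
  e.step_len.resize(n_types); e.redraw_p.resize(n_types);
  e.radius.assign(radius.begin(), radius.end());
  e.max_nb.assign(max_nb.begin(), max_nb.end());
  for (int t = 0; t < n_types; ++t) {
    e.div_p[t] = div_rate_h[t] / 60.0 * dt_phen;
    e.apo_p[t] = apo_rate_h[t] / 60.0 * dt_phen;
    e.step_len[t] = speed[t] * dt_phen;
    e.redraw_p[t] = persistence[t] > 0.0 ?
      std::min(1.0, dt_phen / persistence[t]) : 1.0;
  }
  e.attacker_type = attacker_type - 1;
  e.target_type = target_type - 1;
  e.attack_p = attack_rate * dt_phen;
  e.attack_duration = attack_duration;
  e.kill_prob = kill_prob;
  e.contact_scale = contact_scale;
  e.repulsion = repulsion;
  e.dt_mech = dt_mech;
  e.dt_phen = dt_phen;

  // initial headings for motile agents (one angle draw each, in id order)
  for (int i = 0; i < n; ++i) {
    if (e.step_len[e.type[i]] > 0.0) {
      double a = 2.0 * M_PI * unif_rand();
      e.dirx[i] = std::cos(a); e.diry[i] = std::sin(a);
    }
  }

  int n_sub = (int)std::lround(dt_phen / dt_mech);
  int n_epochs = (int)std::lround(duration / dt_phen);
  int save_every = (int)std::lround(save_interval / dt_phen);

  List snapshots;
  snapshots.push_back(e.snapshot(0.0));

  int n_log = n_epochs;
  IntegerMatrix log(n_log, 4);
  colnames(log) = CharacterVector::create("divisions", "deaths", "kills",
                                          "attacks_started");
  NumericVector log_time(n_log);

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    e.n_div = e.n_apo = e.n_kill = e.n_started = 0;
    for (int s = 0; s < n_sub; ++s) e.mechanics_substep();
    e.migration_step();
    e.division_death_step();
    e.attack_step();
    e.compact();
    double t = epoch * dt_phen;
    log(epoch - 1, 0) = e.n_div;
    log(epoch - 1, 1) = e.n_apo;
    log(epoch - 1, 2) = e.n_kill;
    log(epoch - 1, 3) = e.n_started;
    log_time[epoch - 1] = t;
    if (epoch % save_every == 0) snapshots.push_back(e.snapshot(t));
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["snapshots"] = snapshots,
                      _["log"] = log, _["log_time"] = log_time);
}

// All pairs (i, j), i < j, with center distance <= contact_scale *
// (r_i + r_j), found through the same uniform binning the engine uses.
// Returns a 2-column 1-based index matrix.
// [[Rcpp::export]]
IntegerMatrix close_pairs_cpp(NumericVector x, NumericVector y,
                              NumericVector r, double contact_scale) {
  int n = x.size();
  std::vector<int> out_i, out_j;
  if (n > 0) {
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
    double range = std::max(1e-9, contact_scale * 2.0 * rmax);
    Domain dom = {*std::min_element(x.begin(), x.end()) - 1.0,
                  *std::max_element(x.begin(), x.end()) + 1.0,
                  *std::min_element(y.begin(), y.end()) - 1.0,
                  *std::max_element(y.begin(), y.end()) + 1.0};
    Grid grid;
    grid.setup(dom, range);
    std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
    std::vector<char> alive(n, 1);
    grid.fill(xs, ys, alive);
    for (int i = 0; i < n; ++i) {
      grid.for_neighbors(xs[i], ys[i], [&](int j) {
        if (j <= i) return;
        double thr = contact_scale * (r[i] + r[j]);
        double dx = xs[i] - xs[j], dy = ys[i] - ys[j];
        if (dx * dx + dy * dy <= thr * thr) {
          out_i.push_back(i + 1);
          out_j.push_back(j + 1);
        }
      });
    }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}
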