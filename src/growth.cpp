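// Agent-based branch growth with contact repulsion.
//
// Tips extend by fixed-length steps; each step a tip proposes up to
// n_candidates headings (previous heading + Gaussian noise) and takes the
// first one whose new segment stays in the field and clears the avoidance
// tests; otherwise it stalls permanently.  Proximity queries run against a
// uniform spatial hash grid keyed on avoid_radius.  All randomness comes
// from R's RNG, so results are reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Grid {
  double cell;
  std::unordered_map<long long, std::vector<int> > bins;

  explicit Grid(double cell_size) : cell(cell_size) {}

  static long long key(int gi, int gj) {
    return (static_cast<long long>(gi) << 32) ^
           (static_cast<long long>(gj) & 0xffffffffLL);
  }

  void insert_segment(int id, double x0, double y0, double x1, double y1) {
    int i0 = static_cast<int>(std::floor(std::min(x0, x1) / cell));
    int i1 = static_cast<int>(std::floor(std::max(x0, x1) / cell));
    int j0 = static_cast<int>(std::floor(std::min(y0, y1) / cell));
    int j1 = static_cast<int>(std::floor(std::max(y0, y1) / cell));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[key(i, j)].push_back(id);
  }

  template <typename F>
  void query(double x0, double y0, double x1, double y1, double r, F fun) const {
    int i0 = static_cast<int>(std::floor((std::min(x0, x1) - r) / cell));
    int i1 = static_cast<int>(std::floor((std::max(x0, x1) + r) / cell));
    int j0 = static_cast<int>(std::floor((std::min(y0, y1) - r) / cell));
    int j1 = static_cast<int>(std::floor((std::max(y0, y1) + r) / cell));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
            bins.find(key(i, j));
        if (it == bins.end()) continue;
        const std::vector<int>& v = it->second;
        for (std::size_t k = 0; k < v.size(); ++k) fun(v[k]);
      }
  }
};

inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

// squared minimum distance between segments AB and CD
double seg_seg_dist2(double ax, double ay, double bx, double by,
                     double cx, double cy, double dx, double dy) {
  const double ux = bx - ax, uy = by - ay;
  const double vx = dx - cx, vy = dy - cy;
  const double wx = ax - cx, wy = ay - cy;
  const double a = ux * ux + uy * uy;
  const double b = ux * vx + uy * vy;
  const double c = vx * vx + vy * vy;
  const double d = ux * wx + uy * wy;
  const double e = vx * wx + vy * wy;
  const double den = a * c - b * b;
  double s, t;
  if (den > 1e-12) {
    s = clamp01((b * e - c * d) / den);
  } else {
    s = 0.0;  // nearly parallel
  }
  t = (b * s + e);
  if (c > 1e-12) {
    t = clamp01(t / c);
  } else {
    t = 0.0;
  }
  // re-clamp s for the chosen t
  double s2 = (b * t - d);
  if (a > 1e-12) s2 = clamp01(s2 / a); else s2 = 0.0;
  const double px = ax + s2 * ux - (cx + t * vx);
  const double py = ay + s2 * uy - (cy + t * vy);
  return px * px + py * py;
}

// squared distance from point P to segment AB
inline double pt_seg_dist2(double px, double py, double ax, double ay,
                           double bx, double by) {
  const double ux = bx - ax, uy = by - ay;
  const double len2 = ux * ux + uy * uy;
  double t = 0.0;
  if (len2 > 1e-12) t = clamp01(((px - ax) * ux + (py - ay) * uy) / len2);
  const double dx = ax + t * ux - px;
  const double dy = ay + t * uy - py;
  return dx * dx + dy * dy;
}

// robust segment-segment squared distance: projection solution cross-checked
// with the four point-segment distances
double segdist2(double ax, double ay, double bx, double by,
                double cx, double cy, double dx, double dy) {
  double best = seg_seg_dist2(ax, ay, bx, by, cx, cy, dx, dy);
  double v;
  v = pt_seg_dist2(ax, ay, cx, cy, dx, dy); if (v < best) best = v;
  v = pt_seg_dist2(bx, by, cx, cy, dx, dy); if (v < best) best = v;
  v = pt_seg_dist2(cx, cy, ax, ay, bx, by); if (v < best) best = v;
  v = pt_seg_dist2(dx, dy, ax, ay, bx, by); if (v < best) best = v;
  return best;
}

struct Tip {
  int node;
  double heading;
  int cell;
  bool active;
};

}  // namespace

// [[Rcpp::export(name = ".grow_culture_cpp")]]
List grow_culture_cpp(NumericMatrix somata, int primaries, double step_length,
                      double angle_noise_sd, double branch_prob,
                      double divergence_angle, double avoid_radius,
                      int n_candidate_dirs, int n_steps, bool repulsion,
                      bool self_avoidance, double width, double height,
                      double margin) {
  const int n_cells = somata.nrow();
  const double r2 = avoid_radius * avoid_radius;

  std::vector<double> X, Y;
  std::vector<int> parent, cellid, born;  // born = step index of creation
  X.reserve(4096); Y.reserve(4096);

  Grid grid(std::max(avoid_radius, 1e-6));
  std::vector<int> stamp;  // per-segment visit stamp (segment id = child node)
  int cur_stamp = 0;

  std::vector<Tip> tips;
  for (int c = 0; c < n_cells; ++c) {
    X.push_back(somata(c, 0));
    Y.push_back(somata(c, 1));
    parent.push_back(-1);
    cellid.push_back(c);
    born.push_back(0);
    stamp.push_back(0);
  }
  for (int c = 0; c < n_cells; ++c) {
    for (int p = 0; p < primaries; ++p) {
      Tip t;
      t.node = c;
      t.heading = 2.0 * M_PI * p / primaries + R::norm_rand() * angle_noise_sd;
      t.cell = c;
      t.active = true;
      tips.push_back(t);
    }
  }

  for (int step = 0; step < n_steps; ++step) {
    const std::size_t ntips_now = tips.size();
    bool any_ext = false;
    bool any_active = false;
    for (std::size_t ti = 0; ti < ntips_now; ++ti) {
      Tip& tip = tips[ti];
      if (!tip.active) continue;
      any_active = true;
      const double ax = X[tip.node], ay = Y[tip.node];
      const int e1 = tip.node;
      const int e2 = parent[e1];
      const int e3 = (e2 >= 0) ? parent[e2] : -1;

      int accepted = -1;
      double acc_h = 0.0, bx = 0.0, by = 0.0;
      for (int k = 0; k < n_candidate_dirs; ++k) {
        const double h = tip.heading + R::norm_rand() * angle_noise_sd;
        const double cx = ax + step_length * std::cos(h);
        const double cy = ay + step_length * std::sin(h);
        if (cx < margin || cx > width - margin || cy < margin ||
            cy > height - margin)
          continue;
        bool hit = false;
        if (repulsion) {
          // other cells' somata are occupied space too
          for (int oc = 0; oc < n_cells && !hit; ++oc) {
            if (oc == tip.cell) continue;
            if (pt_seg_dist2(somata(oc, 0), somata(oc, 1), ax, ay, cx, cy) <
                r2)
              hit = true;
          }
        }
        if (!hit && (repulsion || self_avoidance)) {
          ++cur_stamp;
          const int tip_cell = tip.cell;
          grid.query(ax, ay, cx, cy, avoid_radius, [&](int s) {
            if (hit) return;
            if (stamp[s] == cur_stamp) return;
            stamp[s] = cur_stamp;
            const int sc = cellid[s];
            if (sc == tip_cell) {
              if (!self_avoidance) return;
              const int sp = parent[s];
              if (s == e1 || s == e2 || s == e3 || sp == e1 || sp == e2 ||
                  sp == e3)
                return;
            } else {
              if (!repulsion) return;
            }
            const int sp = parent[s];
            if (segdist2(ax, ay, cx, cy, X[sp], Y[sp], X[s], Y[s]) < r2)
              hit = true;
          });
        }
        if (!hit) {
          accepted = k;
          acc_h = h;
          bx = cx;
          by = cy;
          break;
        }
      }

      if (accepted < 0) {
        tip.active = false;
        continue;
      }
      const int new_node = static_cast<int>(X.size());
      X.push_back(bx);
      Y.push_back(by);
      parent.push_back(tip.node);
      cellid.push_back(tip.cell);
      born.push_back(step + 1);
      stamp.push_back(0);
      grid.insert_segment(new_node, ax, ay, bx, by);
      tip.node = new_node;
      tip.heading = acc_h;
      any_ext = true;

      if (branch_prob > 0.0 && R::unif_rand() < branch_prob) {
        Tip t2;
        t2.node = new_node;
        t2.heading = acc_h - divergence_angle / 2.0;
        t2.cell = tip.cell;
        t2.active = true;
        tip.heading = acc_h + divergence_angle / 2.0;
        tips.push_back(t2);
      }
    }
    if (step == 0 && !any_ext)
      stop("no tip could take its first step: avoid_radius (or the field "
           "margin) is degenerate for this configuration");
    if (!any_active) break;
  }

  const int n = static_cast<int>(X.size());
  NumericVector ox(n), oy(n);
  IntegerVector opar(n), ocell(n), oborn(n);
  for (int i = 0; i < n; ++i) {
    ox[i] = X[i];
    oy[i] = Y[i];
    opar[i] = parent[i] + 1;  // 1-based, 0 = root
    ocell[i] = cellid[i] + 1;
    oborn[i] = born[i];
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["parent"] = opar,
                      _["cell"] = ocell, _["born"] = oborn);
}
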