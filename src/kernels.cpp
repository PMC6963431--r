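#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Numeric hot spots of the simulator: rigid-cluster integration, positional
// collision resolution, proximity pair queries and bond-graph components.
// All stochastic draws happen on the R side; these kernels are deterministic.

static inline int slot_of(std::unordered_map<int, int> &map, int id,
                          int &next) {
  auto it = map.find(id);
  if (it != map.end()) return it->second;
  map[id] = next;
  return next++;
}

// Connected components of the bond graph given per-site partner indices
// (1-based, 0 = free site). Labels are compacted to 1..K in order of first
// appearance so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector bond_a, IntegerVector bond_b) {
  const int n = bond_a.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  auto find = [&](int v) {
    while (parent[v] != v) {
      parent[v] = parent[parent[v]];
      v = parent[v];
    }
    return v;
  };
  auto unite = [&](int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int i = 0; i < n; ++i) {
    if (bond_a[i] > 0) unite(i, bond_a[i] - 1);
    if (bond_b[i] > 0) unite(i, bond_b[i] - 1);
  }
  IntegerVector out(n);
  std::unordered_map<int, int> label;
  int next = 1;
  for (int i = 0; i < n; ++i) out[i] = slot_of(label, find(i), next);
  return out;
}

// ---------------------------------------------------------------------------
// shared cores

struct Clusters {
  int K;
  std::vector<int> cl;                 // compacted cluster slot per body
  std::vector<double> M;               // cluster mass
  std::vector<std::vector<int> > members;
};

static Clusters build_clusters(const IntegerVector &cluster,
                               const NumericVector &mass) {
  Clusters C;
  const int n = cluster.size();
  std::unordered_map<int, int> slot;
  C.K = 0;
  C.cl.resize(n);
  for (int i = 0; i < n; ++i) C.cl[i] = slot_of(slot, cluster[i], C.K);
  C.M.assign(C.K, 0.0);
  C.members.resize(C.K);
  for (int i = 0; i < n; ++i) {
    C.M[C.cl[i]] += mass[i];
    C.members[C.cl[i]].push_back(i);
  }
  return C;
}

// Semi-implicit step for a mixed population of rigid clusters and free
// particles: cluster velocity += net force / mass * dt, *= damping; members
// rotate about the centroid by the torque-driven spin and translate
// together; reflecting walls applied cluster-rigidly.
static void integrate_core(const Clusters &C, std::vector<double> &x,
                           std::vector<double> &y, std::vector<double> &vx,
                           std::vector<double> &vy, std::vector<double> &om,
                           std::vector<double> &orient,
                           const NumericVector &mass,
                           const NumericVector &radius, const double *fx,
                           const double *fy, double dt, double damping,
                           double W, double H) {
  const int n = x.size();
  const int K = C.K;
  std::vector<double> CX(K, 0.0), CY(K, 0.0), FX(K, 0.0), FY(K, 0.0),
      TQ(K, 0.0), I(K, 0.0), V_X(K), V_Y(K), OM(K);
  for (int i = 0; i < n; ++i) {
    int c = C.cl[i];
    CX[c] += mass[i] * x[i];
    CY[c] += mass[i] * y[i];
    if (fx) {
      FX[c] += fx[i];
      FY[c] += fy[i];
    }
  }
  for (int c = 0; c < K; ++c) {
    CX[c] /= C.M[c];
    CY[c] /= C.M[c];
  }
  for (int i = 0; i < n; ++i) {
    int c = C.cl[i];
    double rx = x[i] - CX[c], ry = y[i] - CY[c];
    if (fx) TQ[c] += rx * fy[i] - ry * fx[i];
    I[c] += mass[i] * (rx * rx + ry * ry + 0.5 * radius[i] * radius[i]);
  }
  for (int c = 0; c < K; ++c) {
    int f = C.members[c][0]; // members share the cluster velocity
    V_X[c] = (vx[f] + FX[c] / C.M[c] * dt) * damping;
    V_Y[c] = (vy[f] + FY[c] / C.M[c] * dt) * damping;
    OM[c] = (om[f] + TQ[c] / I[c] * dt) * damping;
  }
  for (int i = 0; i < n; ++i) {
    int c = C.cl[i];
    double dth = OM[c] * dt;
    double ca = std::cos(dth), sa = std::sin(dth);
    double rx = x[i] - CX[c], ry = y[i] - CY[c];
    x[i] = CX[c] + ca * rx - sa * ry + V_X[c] * dt;
    y[i] = CY[c] + sa * rx + ca * ry + V_Y[c] * dt;
    orient[i] += dth;
  }
  // reflecting walls
  std::vector<double> minx(K, R_PosInf), maxx(K, R_NegInf),
      miny(K, R_PosInf), maxy(K, R_NegInf);
  for (int i = 0; i < n; ++i) {
    int c = C.cl[i];
    minx[c] = std::min(minx[c], x[i] - radius[i]);
    maxx[c] = std::max(maxx[c], x[i] + radius[i]);
    miny[c] = std::min(miny[c], y[i] - radius[i]);
    maxy[c] = std::max(maxy[c], y[i] + radius[i]);
  }
  for (int c = 0; c < K; ++c) {
    double sx = 0, sy = 0;
    if (minx[c] < 0) {
      sx = -minx[c];
      if (V_X[c] < 0) V_X[c] = -V_X[c];
    } else if (maxx[c] > W) {
      sx = W - maxx[c];
      if (V_X[c] > 0) V_X[c] = -V_X[c];
    }
    if (miny[c] < 0) {
      sy = -miny[c];
      if (V_Y[c] < 0) V_Y[c] = -V_Y[c];
    } else if (maxy[c] > H) {
      sy = H - maxy[c];
      if (V_Y[c] > 0) V_Y[c] = -V_Y[c];
    }
    if (sx != 0 || sy != 0) {
      for (int m : C.members[c]) {
        x[m] += sx;
        y[m] += sy;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    int c = C.cl[i];
    vx[i] = V_X[c];
    vy[i] = V_Y[c];
    om[i] = OM[c];
  }
}

// Positional overlap correction between discs of different clusters:
// Gauss-Seidel passes over a uniform-grid broad phase; each overlapping
// pair is separated along the centre line, split inversely by cluster mass
// and applied to whole clusters so bonded geometry is preserved. Clusters
// are clamped back inside the tray after every pass.
static void resolve_core(const Clusters &C, std::vector<double> &x,
                         std::vector<double> &y, const NumericVector &radius,
                         int passes, double tol, double W, double H) {
  const int n = x.size();
  if (n < 2) return;
  auto shift_cluster = [&](int c, double dx, double dy) {
    for (int m : C.members[c]) {
      x[m] += dx;
      y[m] += dy;
    }
  };
  auto clamp_walls = [&]() {
    for (int c = 0; c < C.K; ++c) {
      double mnx = R_PosInf, mxx = R_NegInf, mny = R_PosInf,
             mxy = R_NegInf;
      for (int m : C.members[c]) {
        mnx = std::min(mnx, x[m] - radius[m]);
        mxx = std::max(mxx, x[m] + radius[m]);
        mny = std::min(mny, y[m] - radius[m]);
        mxy = std::max(mxy, y[m] + radius[m]);
      }
      double dx = 0, dy = 0;
      if (mnx < 0) dx = -mnx; else if (mxx > W) dx = W - mxx;
      if (mny < 0) dy = -mny; else if (mxy > H) dy = H - mxy;
      if (dx != 0 || dy != 0) shift_cluster(c, dx, dy);
    }
  };

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
  const double cell = std::max(2.0 * rmax, 1e-6);
  const int gx = std::max(1, (int)(W / cell));
  const int gy = std::max(1, (int)(H / cell));
  std::vector<std::vector<int> > bins(gx * gy);
  auto bin_of = [&](double px, double py) {
    int bx = std::min(gx - 1, std::max(0, (int)(px / cell)));
    int by = std::min(gy - 1, std::max(0, (int)(py / cell)));
    return by * gx + bx;
  };

  for (int pass = 0; pass < passes; ++pass) {
    bool changed = false;
    for (auto &b : bins) b.clear();
    for (int i = 0; i < n; ++i) bins[bin_of(x[i], y[i])].push_back(i);
    for (int by = 0; by < gy; ++by) {
      for (int bx = 0; bx < gx; ++bx) {
        const std::vector<int> &me = bins[by * gx + bx];
        if (me.empty()) continue;
        for (int oy = std::max(0, by - 1);
             oy <= std::min(gy - 1, by + 1); ++oy) {
          for (int ox = std::max(0, bx - 1);
               ox <= std::min(gx - 1, bx + 1); ++ox) {
            const std::vector<int> &other = bins[oy * gx + ox];
            for (int i : me) {
              for (int j : other) {
                if (j <= i || C.cl[i] == C.cl[j]) continue;
                double dx = x[j] - x[i], dy = y[j] - y[i];
                double target = radius[i] + radius[j];
                double d2 = dx * dx + dy * dy;
                if (d2 >= target * target) continue;
                double d = std::sqrt(d2);
                double overlap = target - d;
                if (overlap <= tol) continue;
                double ux, uy;
                if (d > 1e-12) {
                  ux = dx / d;
                  uy = dy / d;
                } else { // coincident centres: deterministic direction
                  ux = 1.0;
                  uy = 0.0;
                }
                double wi = C.M[C.cl[j]] / (C.M[C.cl[i]] + C.M[C.cl[j]]);
                shift_cluster(C.cl[i], -ux * overlap * wi,
                              -uy * overlap * wi);
                shift_cluster(C.cl[j], ux * overlap * (1.0 - wi),
                              uy * overlap * (1.0 - wi));
                changed = true;
              }
            }
          }
        }
      }
    }
    clamp_walls();
    if (!changed) break;
  }
}

static std::vector<double> as_vec(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// exported wrappers

// [[Rcpp::export]]
List cpp_integrate(NumericVector x, NumericVector y, NumericVector vx,
                   NumericVector vy, NumericVector om, NumericVector orient,
                   IntegerVector cluster, NumericVector mass,
                   NumericVector radius, NumericVector fx, NumericVector fy,
                   double dt, double damping, double W, double H) {
  Clusters C = build_clusters(cluster, mass);
  std::vector<double> X = as_vec(x), Y = as_vec(y), VX = as_vec(vx),
                      VY = as_vec(vy), OM = as_vec(om), OR = as_vec(orient);
  integrate_core(C, X, Y, VX, VY, OM, OR, mass, radius,
                 fx.size() ? &fx[0] : nullptr, fy.size() ? &fy[0] : nullptr,
                 dt, damping, W, H);
  return List::create(_["x"] = wrap(X), _["y"] = wrap(Y), _["vx"] = wrap(VX),
                      _["vy"] = wrap(VY), _["om"] = wrap(OM),
                      _["orient"] = wrap(OR));
}

// [[Rcpp::export]]
List cpp_resolve(NumericVector x, NumericVector y, NumericVector radius,
                 IntegerVector cluster, NumericVector mass, int passes,
                 double tol, double W, double H) {
  Clusters C = build_clusters(cluster, mass);
  std::vector<double> X = as_vec(x), Y = as_vec(y);
  resolve_core(C, X, Y, radius, passes, tol, W, H);
  return List::create(_["x"] = wrap(X), _["y"] = wrap(Y));
}

// fused physics step + collision resolution (one call per iteration in the
// run loop; numerics identical to cpp_integrate followed by cpp_resolve)
// [[Rcpp::export]]
List cpp_advance(NumericVector x, NumericVector y, NumericVector vx,
                 NumericVector vy, NumericVector om, NumericVector orient,
                 IntegerVector cluster, NumericVector mass,
                 NumericVector radius, NumericVector fx, NumericVector fy,
                 double dt, double damping, int passes, double tol,
                 double W, double H) {
  Clusters C = build_clusters(cluster, mass);
  std::vector<double> X = as_vec(x), Y = as_vec(y), VX = as_vec(vx),
                      VY = as_vec(vy), OM = as_vec(om), OR = as_vec(orient);
  integrate_core(C, X, Y, VX, VY, OM, OR, mass, radius,
                 fx.size() ? &fx[0] : nullptr, fy.size() ? &fy[0] : nullptr,
                 dt, damping, W, H);
  resolve_core(C, X, Y, radius, passes, tol, W, H);
  return List::create(_["x"] = wrap(X), _["y"] = wrap(Y), _["vx"] = wrap(VX),
                      _["vy"] = wrap(VY), _["om"] = wrap(OM),
                      _["orient"] = wrap(OR));
}

// All cross pairs (i from set 1, j from set 2) with euclidean distance
// <= maxd, sorted by distance then indices (1-based). Used for trigger-zone
// candidate enumeration; candidate sets are small.
// [[Rcpp::export]]
List cpp_pairs_within(NumericVector x1, NumericVector y1, NumericVector x2,
                      NumericVector y2, double maxd) {
  const int n1 = x1.size(), n2 = x2.size();
  std::vector<int> ii, jj;
  std::vector<double> dd;
  const double m2 = maxd * maxd;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double dx = x2[j] - x1[i], dy = y2[j] - y1[i];
      double d2 = dx * dx + dy * dy;
      if (d2 <= m2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  const int m = ii.size();
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (dd[a] != dd[b]) return dd[a] < dd[b];
    if (ii[a] != ii[b]) return ii[a] < ii[b];
    return jj[a] < jj[b];
  });
  IntegerVector oi(m), oj(m);
  NumericVector od(m);
  for (int k = 0; k < m; ++k) {
    oi[k] = ii[ord[k]];
    oj[k] = jj[ord[k]];
    od[k] = dd[ord[k]];
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["d"] = od);
}

// Maximum pairwise overlap between discs of different clusters (brute
// force); used by tests and the collision-resolution stopping contract.
// [[Rcpp::export]]
double cpp_max_overlap(NumericVector x, NumericVector y, NumericVector radius,
                       IntegerVector cluster) {
  const int n = x.size();
  double worst = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (cluster[i] == cluster[j]) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      double ov = radius[i] + radius[j] - d;
      if (ov > worst) worst = ov;
    }
  }
  return worst;
}
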