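// Compiled evolution engine: the generation loop of the NSGA-II search
// with stochastic Pareto dominance.  Semantics mirror the exported R step
// functions (mutate, stochastic_nondominated_sort, crowding_distance,
// select_parents, evolve_generation); the R and compiled evaluation /
// placement primitives are cross-checked in the test suite.
//
// All randomness flows through R's RNG (unif_rand / norm_rand), so a
// set.seed() before the call makes a run fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

namespace {

struct Genome {
  // weights[l]: column-major (n_l x n_{l+1}); 0 = absent connection
  std::vector<std::vector<double>> W;
  // thresholds[l]: one per node, including (inert) input thresholds
  std::vector<std::vector<double>> b;
};

struct Problem {
  std::vector<int> layers;
  std::vector<double> X;          // npat x nin, column-major
  int npat = 0;
  // one target set per environment (MVG uses two), npat x nout, 0/1
  std::vector<std::vector<double>> targets;
  int nout = 0;
  int mvg_period = 0;             // 0 = static environment
  std::vector<double> fixed_x, fixed_y;  // inputs then outputs
  double lambda = 20.0, bias_sign = -1.0;
};

struct Params {
  int treatment = 1;   // 0 PA, 1 PCC_length, 2 PCC_count, 3 PRO
  double p_cost = 0.25;
  int pop_size = 100;
  int generations = 100;
  double r_add = 0.20, r_remove = 0.20, r_thresh = 1.0 / 24.0,
         r_weight = 2.0;
  int real_mode = 0;
  double sigma = 0.5;
  double stop_at = 2.0;          // break when best perf >= stop_at
  int snap_every = 0;
};

// tanh with a saturation fast path: for |x| > 19, tanh(x) is 1 - 2e^{-2x}
// with 2e^{-2x} < DBL_EPSILON/2, so the result equals +-1.0 exactly and
// the fast path is bit-identical to std::tanh
inline double tanh_sat(double x) {
  if (x > 19.0) return 1.0;
  if (x < -19.0) return -1.0;
  return std::tanh(x);
}

Genome genome_from_r(const List& gl) {
  Genome g;
  List Wl = gl["weights"];
  List bl = gl["thresholds"];
  for (int l = 0; l < Wl.size(); ++l) {
    NumericMatrix w = as<NumericMatrix>(Wl[l]);
    g.W.emplace_back(w.begin(), w.end());
  }
  for (int l = 0; l < bl.size(); ++l) {
    NumericVector b = as<NumericVector>(bl[l]);
    g.b.emplace_back(b.begin(), b.end());
  }
  return g;
}

List genome_to_r(const Genome& g, const std::vector<int>& layers,
                 bool real_mode) {
  int L = layers.size();
  List Wl(L - 1), bl(L);
  for (int l = 0; l < L - 1; ++l) {
    NumericMatrix w(layers[l], layers[l + 1]);
    std::copy(g.W[l].begin(), g.W[l].end(), w.begin());
    Wl[l] = w;
  }
  for (int l = 0; l < L; ++l) bl[l] = wrap(g.b[l]);
  return List::create(_["layers"] = wrap(layers), _["weights"] = Wl,
                      _["thresholds"] = bl,
                      _["mode"] = real_mode ? "real" : "integer");
}

int count_connections(const Genome& g) {
  int n = 0;
  for (const auto& w : g.W)
    for (double v : w) if (v != 0.0) ++n;
  return n;
}

// fraction of correct classified answers over all patterns and outputs
double eval_performance(const Genome& g, const Problem& pb, int env_idx) {
  int L = pb.layers.size();
  int npat = pb.npat;
  static thread_local std::vector<double> act_a, act_b;
  const std::vector<double>* prev = &pb.X;
  std::vector<double>* cur = &act_a;
  std::vector<double>* spare = &act_b;
  for (int l = 1; l < L; ++l) {
    int nin = pb.layers[l - 1], nout = pb.layers[l];
    cur->assign((size_t)npat * nout, 0.0);
    const std::vector<double>& w = g.W[l - 1];
    for (int j = 0; j < nout; ++j) {
      double* out = cur->data() + (size_t)j * npat;
      for (int i = 0; i < nin; ++i) {
        double wij = w[i + (size_t)j * nin];
        if (wij == 0.0) continue;
        const double* in = prev->data() + (size_t)i * npat;
        for (int p = 0; p < npat; ++p) out[p] += wij * in[p];
      }
      double bj = pb.bias_sign * g.b[l][j];
      for (int p = 0; p < npat; ++p)
        out[p] = tanh_sat(pb.lambda * (out[p] + bj));
    }
    prev = cur;
    std::swap(cur, spare);
  }
  const std::vector<double>& out = *prev;
  const std::vector<double>& tg = pb.targets[env_idx];
  int correct = 0;
  int ntot = npat * pb.nout;
  for (int k = 0; k < ntot; ++k) {
    bool ans = out[k] >= 0.0;
    bool t = tg[k] != 0.0;
    if (ans == t) ++correct;
  }
  return (double)correct / ntot;
}

// summed squared connection length with hidden nodes optimally placed
double placement_cost(const Genome& g, const Problem& pb) {
  int L = pb.layers.size();
  int N = 0;
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) { off[l] = N; N += pb.layers[l]; }
  off[L] = N;
  int nin = pb.layers[0], nout = pb.layers[L - 1];

  // adjacency list
  std::vector<std::vector<int>> adj(N);
  std::vector<std::pair<int, int>> edges;
  for (int l = 0; l < L - 1; ++l) {
    int a = pb.layers[l], bsz = pb.layers[l + 1];
    const std::vector<double>& w = g.W[l];
    for (int j = 0; j < bsz; ++j)
      for (int i = 0; i < a; ++i)
        if (w[i + (size_t)j * a] != 0.0) {
          int u = off[l] + i, v = off[l + 1] + j;
          adj[u].push_back(v);
          adj[v].push_back(u);
          edges.emplace_back(u, v);
        }
  }
  if (edges.empty()) return 0.0;

  std::vector<double> x(N, 0.0), y(N, 0.0);
  std::vector<char> fixed(N, 0), reach(N, 0);
  for (int i = 0; i < nin; ++i) {
    x[i] = pb.fixed_x[i]; y[i] = pb.fixed_y[i]; fixed[i] = 1;
  }
  for (int j = 0; j < nout; ++j) {
    int v = off[L - 1] + j;
    x[v] = pb.fixed_x[nin + j]; y[v] = pb.fixed_y[nin + j]; fixed[v] = 1;
  }

  // BFS from fixed nodes; unreached components collapse to a point
  std::vector<int> stack;
  for (int i = 0; i < N; ++i) if (fixed[i]) { reach[i] = 1; stack.push_back(i); }
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int v : adj[u]) if (!reach[v]) { reach[v] = 1; stack.push_back(v); }
  }

  std::vector<int> freeid(N, -1), freenodes;
  for (int i = 0; i < N; ++i)
    if (!fixed[i] && reach[i] && !adj[i].empty()) {
      freeid[i] = freenodes.size();
      freenodes.push_back(i);
    }
  int nf = freenodes.size();
  if (nf > 0) {
    // Laplacian system, solved per axis by Gaussian elimination
    std::vector<double> A((size_t)nf * nf, 0.0), rx(nf, 0.0), ry(nf, 0.0);
    for (int k = 0; k < nf; ++k) {
      int u = freenodes[k];
      A[k + (size_t)k * nf] = adj[u].size();
      for (int v : adj[u]) {
        if (freeid[v] >= 0) A[k + (size_t)freeid[v] * nf] -= 1.0;
        else if (fixed[v]) { rx[k] += x[v]; ry[k] += y[v]; }
        // neighbours in unreached components are impossible here
      }
    }
    for (int c = 0; c < nf; ++c) {       // partial pivoting
      int piv = c;
      for (int r = c + 1; r < nf; ++r)
        if (std::fabs(A[r + (size_t)c * nf]) >
            std::fabs(A[piv + (size_t)c * nf])) piv = r;
      if (piv != c) {
        for (int cc = 0; cc < nf; ++cc)
          std::swap(A[c + (size_t)cc * nf], A[piv + (size_t)cc * nf]);
        std::swap(rx[c], rx[piv]);
        std::swap(ry[c], ry[piv]);
      }
      double d = A[c + (size_t)c * nf];
      for (int r = c + 1; r < nf; ++r) {
        double f = A[r + (size_t)c * nf] / d;
        if (f == 0.0) continue;
        for (int cc = c; cc < nf; ++cc)
          A[r + (size_t)cc * nf] -= f * A[c + (size_t)cc * nf];
        rx[r] -= f * rx[c];
        ry[r] -= f * ry[c];
      }
    }
    for (int r = nf - 1; r >= 0; --r) {
      double sx = rx[r], sy = ry[r];
      for (int cc = r + 1; cc < nf; ++cc) {
        sx -= A[r + (size_t)cc * nf] * x[freenodes[cc]];
        sy -= A[r + (size_t)cc * nf] * y[freenodes[cc]];
      }
      x[freenodes[r]] = sx / A[r + (size_t)r * nf];
      y[freenodes[r]] = sy / A[r + (size_t)r * nf];
    }
  }

  double cost = 0.0;
  for (auto& e : edges) {
    if (!reach[e.first]) continue;  // collapsed component, zero length
    double dx = x[e.first] - x[e.second], dy = y[e.first] - y[e.second];
    cost += dx * dx + dy * dy;
  }
  return cost;
}

// mutation: add, remove, thresholds, weights, in that fixed order
void mutate_genome(Genome& g, const Problem& pb, const Params& pr) {
  int nl = g.W.size();
  // (i) add a connection
  if (unif_rand() < pr.r_add) {
    int tot = 0;
    for (auto& w : g.W) for (double v : w) if (v == 0.0) ++tot;
    if (tot > 0) {
      int k = (int)(unif_rand() * tot);
      if (k >= tot) k = tot - 1;
      for (int l = 0; l < nl && k >= 0; ++l) {
        for (auto& v : g.W[l]) {
          if (v == 0.0) {
            if (k == 0) {
              if (pr.real_mode) {
                double nv = unif_rand() * 4.0 - 2.0;
                v = (nv == 0.0) ? 1e-6 : nv;
              } else {
                static const double vals[4] = {-2, -1, 1, 2};
                int vi = (int)(unif_rand() * 4.0);
                if (vi > 3) vi = 3;
                v = vals[vi];
              }
              k = -1;
              break;
            }
            --k;
          }
        }
      }
    }
  }
  // (ii) remove a connection
  if (unif_rand() < pr.r_remove) {
    int tot = count_connections(g);
    if (tot > 0) {
      int k = (int)(unif_rand() * tot);
      if (k >= tot) k = tot - 1;
      for (int l = 0; l < nl && k >= 0; ++l) {
        for (auto& v : g.W[l]) {
          if (v != 0.0) {
            if (k == 0) { v = 0.0; k = -1; break; }
            --k;
          }
        }
      }
    }
  }
  // (iii) thresholds, per node
  for (auto& bl : g.b) {
    for (auto& b : bl) {
      if (unif_rand() < pr.r_thresh) {
        if (pr.real_mode) {
          double nb = b + norm_rand() * pr.sigma;
          b = std::min(2.0, std::max(-2.0, nb));
        } else {
          double step = unif_rand() < 0.5 ? -1.0 : 1.0;
          double nb = b + step;
          if (std::fabs(nb) <= 2.0) b = nb;
        }
      }
    }
  }
  // (iv) weights, per connection with probability r_weight / n
  int ncon = count_connections(g);
  if (ncon > 0) {
    double pw = std::min(1.0, pr.r_weight / ncon);
    for (auto& w : g.W) {
      for (auto& v : w) {
        if (v != 0.0 && unif_rand() < pw) {
          if (pr.real_mode) {
            double nv = std::min(2.0, std::max(-2.0, v + norm_rand() *
                                               pr.sigma));
            if (nv == 0.0) nv = 1e-6;
            v = nv;
          } else {
            double step = unif_rand() < 0.5 ? -1.0 : 1.0;
            double nv = v + step;
            if (nv == 0.0) nv = v + 2.0 * step;  // 0 is not a weight
            if (std::fabs(nv) <= 2.0) v = nv;
          }
        }
      }
    }
  }
}

// stochastic non-dominated sort; sec empty = single objective.
// one fresh r per ordered pairwise test
std::vector<int> stoch_sort(const std::vector<double>& perf,
                            const std::vector<double>& sec,
                            double p) {
  int n = perf.size();
  std::vector<int> rank(n, 0);
  bool two = !sec.empty();
  std::vector<uint8_t> D((size_t)n * n, 0);  // D[i + j*n]: i dominates j
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      bool d;
      if (!two) {
        d = perf[i] > perf[j];
      } else {
        double r = unif_rand();
        if (r > p) d = perf[i] > perf[j];
        else d = (perf[i] >= perf[j] && sec[i] >= sec[j]) &&
                 (perf[i] > perf[j] || sec[i] > sec[j]);
      }
      D[i + (size_t)j * n] = d;
    }
  }
  std::vector<char> remaining(n, 1);
  int assigned = 0, layer = 0;
  std::vector<int> rem;
  rem.reserve(n);
  for (int i = 0; i < n; ++i) rem.push_back(i);
  while (assigned < n) {
    ++layer;
    std::vector<int> this_layer, next_rem;
    for (int j : rem) {
      bool dominated = false;
      for (int i : rem)
        if (D[i + (size_t)j * n]) { dominated = true; break; }
      if (!dominated) this_layer.push_back(j);
    }
    if (this_layer.empty()) this_layer = rem;  // unreachable safety
    for (int j : this_layer) rank[j] = layer;
    assigned += this_layer.size();
    for (int j : rem)
      if (rank[j] == 0) next_rem.push_back(j);
    rem.swap(next_rem);
  }
  return rank;
}

std::vector<double> crowding(const std::vector<double>& perf,
                             const std::vector<double>& sec,
                             const std::vector<int>& rank) {
  int n = perf.size();
  std::vector<double> crowd(n, 0.0);
  int maxrank = *std::max_element(rank.begin(), rank.end());
  int nobj = sec.empty() ? 1 : 2;
  for (int k = 1; k <= maxrank; ++k) {
    std::vector<int> m;
    for (int i = 0; i < n; ++i) if (rank[i] == k) m.push_back(i);
    if (m.empty()) continue;
    int sz = m.size();
    for (int obj = 0; obj < nobj; ++obj) {
      const std::vector<double>& v = obj == 0 ? perf : sec;
      std::vector<int> ord(m);
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return v[a] < v[b]; });
      double rng = v[ord[sz - 1]] - v[ord[0]];
      crowd[ord[0]] = R_PosInf;
      crowd[ord[sz - 1]] = R_PosInf;
      if (sz > 2 && rng > 0)
        for (int t = 1; t < sz - 1; ++t)
          if (crowd[ord[t]] != R_PosInf)
            crowd[ord[t]] += (v[ord[t + 1]] - v[ord[t - 1]]) / rng;
    }
  }
  return crowd;
}

bool stoch_dom_pair(double p1, double s1, double p2, double s2, bool two,
                    double p) {
  if (!two) return p1 > p2;
  double r = unif_rand();
  if (r > p) return p1 > p2;
  return (p1 >= p2 && s1 >= s2) && (p1 > p2 || s1 > s2);
}

// ---- modularity maximization ----------------------------------------------
// Mirrors the R reference implementation: greedy agglomeration,
// single-node refinement, whole-community merges, recursive bisection;
// best of three deterministic initializations, ties broken by lowest
// index.

struct QProblem {
  int n;
  std::vector<double> B;  // modularity contribution matrix, column-major
  std::vector<double> S;  // B + t(B)
  double diag_sum;
};

double q_quality(const QProblem& qp, const std::vector<int>& memb) {
  double q = qp.diag_sum;
  for (int i = 0; i < qp.n; ++i)
    for (int j = i + 1; j < qp.n; ++j)
      if (memb[i] == memb[j]) q += qp.S[i + (size_t)j * qp.n];
  return q;
}

void relabel(std::vector<int>& memb) {
  std::vector<int> map(memb.size(), -1);
  int next = 0;
  for (auto& m : memb) {
    if (map[m] < 0) map[m] = next++;
    m = map[m];
  }
}

std::vector<int> q_greedy_agglomerate(const QProblem& qp) {
  int n = qp.n;
  std::vector<int> memb(n);
  std::iota(memb.begin(), memb.end(), 0);
  std::vector<double> G(qp.S);
  std::vector<char> alive(n, 1);
  for (;;) {
    double best = -1.0;
    int bu = -1, bv = -1;
    for (int v = 1; v < n; ++v) {
      if (!alive[v]) continue;
      for (int u = 0; u < v; ++u) {
        if (!alive[u]) continue;
        double g = G[u + (size_t)v * n];
        if (g > best) { best = g; bu = u; bv = v; }
      }
    }
    if (bu < 0 || best <= 1e-12) break;
    for (auto& m : memb) if (m == bv) m = bu;
    for (int w = 0; w < n; ++w) {
      if (!alive[w] || w == bu || w == bv) continue;
      double g = G[std::min(bu, w) + (size_t)std::max(bu, w) * n] +
                 G[std::min(bv, w) + (size_t)std::max(bv, w) * n];
      G[std::min(bu, w) + (size_t)std::max(bu, w) * n] = g;
    }
    alive[bv] = 0;
  }
  relabel(memb);
  return memb;
}

void q_kl_refine(const QProblem& qp, std::vector<int>& memb) {
  int n = qp.n;
  relabel(memb);
  int nc = *std::max_element(memb.begin(), memb.end()) + 1;
  // SM[i][c]: link of node i into community c (self included)
  std::vector<std::vector<double>> SM(n, std::vector<double>(nc + 1, 0.0));
  auto Sat = [&](int i, int j) { return qp.S[std::min(i, j) +
                                            (size_t)std::max(i, j) * n]; };
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      SM[i][memb[j]] += (i == j) ? qp.S[i + (size_t)i * n] : Sat(i, j);
  int empty_col = nc;
  for (;;) {
    bool improved = false;
    for (int i = 0; i < n; ++i) {
      int cur = memb[i];
      double self = qp.S[i + (size_t)i * n];
      double li_cur = SM[i][cur] - self;
      double best_gain = 1e-12;
      int best_c = -1;
      int ncols = SM[i].size();
      for (int c = 0; c < ncols; ++c) {
        if (c == cur) continue;
        double gain = SM[i][c] - li_cur;
        if (gain > best_gain) { best_gain = gain; best_c = c; }
      }
      if (best_c >= 0) {
        memb[i] = best_c;
        for (int j = 0; j < n; ++j) {
          double sij = (i == j) ? qp.S[i + (size_t)i * n] : Sat(i, j);
          SM[j][cur] -= sij;
          SM[j][best_c] += sij;
        }
        if (best_c == empty_col) {
          for (int j = 0; j < n; ++j) SM[j].push_back(0.0);
          ++empty_col;
        }
        improved = true;
      }
    }
    if (!improved) break;
  }
  relabel(memb);
}

void q_merge_phase(const QProblem& qp, std::vector<int>& memb) {
  int n = qp.n;
  for (;;) {
    relabel(memb);
    int nc = *std::max_element(memb.begin(), memb.end()) + 1;
    if (nc == 1) return;
    std::vector<double> M((size_t)nc * nc, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j)
          M[memb[i] + (size_t)memb[j] * nc] +=
            qp.S[std::min(i, j) + (size_t)std::max(i, j) * n] / 2.0;
    double best = -1.0;
    int bu = -1, bv = -1;
    for (int v = 1; v < nc; ++v)
      for (int u = 0; u < v; ++u) {
        double g = M[u + (size_t)v * nc] + M[v + (size_t)u * nc];
        if (g > best) { best = g; bu = u; bv = v; }
      }
    if (bu < 0 || best <= 1e-12) return;
    for (auto& m : memb) if (m == bv) m = bu;
  }
}

// 2-colouring of a community maximizing the within-side pair sum
std::vector<int> q_two_colouring(const QProblem& qp,
                                 const std::vector<int>& C) {
  int m = C.size();
  std::vector<int> side(m, 0);
  auto Sat = [&](int i, int j) { return qp.S[std::min(i, j) +
                                            (size_t)std::max(i, j) * qp.n]; };
  if (m <= 12) {
    long best_cfg = -1;
    double best_q = -1e300;
    long ncfg = 1L << (m - 1);
    for (long cfg = 1; cfg < ncfg; ++cfg) {
      double q = 0.0;
      for (int i = 0; i < m - 1; ++i) {
        bool si = i > 0 && (cfg >> (i - 1)) & 1L;
        for (int j = i + 1; j < m; ++j) {
          bool sj = (cfg >> (j - 1)) & 1L;
          if (si == sj) q += Sat(C[i], C[j]);
        }
      }
      if (q > best_q) { best_q = q; best_cfg = cfg; }
    }
    for (int j = 1; j < m; ++j)
      side[j] = (best_cfg >> (j - 1)) & 1L;
    return side;
  }
  // power iteration for the leading eigenvector of the shifted submatrix
  std::vector<double> v(m);
  for (int i = 0; i < m; ++i) v[i] = 1.0 + 1e-3 * i;
  double shift = 0.0;
  for (int i = 0; i < m; ++i) {
    double rs = 0.0;
    for (int j = 0; j < m; ++j) rs += std::fabs(Sat(C[i], C[j]));
    shift = std::max(shift, rs);
  }
  for (int it = 0; it < 200; ++it) {
    std::vector<double> w(m, 0.0);
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < m; ++j) w[i] += Sat(C[i], C[j]) * v[j];
      w[i] += shift * v[i];
    }
    double norm = 0.0;
    for (double x : w) norm += x * x;
    norm = std::sqrt(norm);
    if (norm == 0.0) break;
    for (int i = 0; i < m; ++i) v[i] = w[i] / norm;
  }
  bool any1 = false, any0 = false;
  for (int i = 0; i < m; ++i) {
    side[i] = v[i] >= 0 ? 0 : 1;
    (side[i] ? any1 : any0) = true;
  }
  if (!any1 || !any0) side[0] = 1 - side[0];
  // greedy side swaps keeping both sides non-empty
  for (;;) {
    bool improved = false;
    for (int i = 0; i < m; ++i) {
      int cnt = 0;
      for (int j = 0; j < m; ++j) if (side[j] == side[i]) ++cnt;
      if (cnt == 1) continue;
      double gain = 0.0;
      for (int j = 0; j < m; ++j) {
        if (j == i) continue;
        gain += (side[j] != side[i] ? 1.0 : -1.0) * Sat(C[i], C[j]);
      }
      if (gain > 1e-12) { side[i] = 1 - side[i]; improved = true; }
    }
    if (!improved) break;
  }
  return side;
}

std::vector<int> q_bisection_init(const QProblem& qp) {
  int n = qp.n;
  std::vector<int> memb(n, 0);
  std::vector<std::vector<int>> queue;
  std::vector<int> all(n);
  std::iota(all.begin(), all.end(), 0);
  queue.push_back(all);
  int next_label = 1;
  while (!queue.empty()) {
    std::vector<int> C = queue.front();
    queue.erase(queue.begin());
    if (C.size() < 2) continue;
    std::vector<int> side = q_two_colouring(qp, C);
    double cross = 0.0;
    for (size_t a = 0; a < C.size(); ++a)
      for (size_t b = 0; b < C.size(); ++b)
        if (a != b && side[a] == 0 && side[b] == 1)
          cross += qp.S[std::min(C[a], C[b]) +
                        (size_t)std::max(C[a], C[b]) * n] / 2.0;
    if (-cross <= 1e-12) continue;  // split must gain Q
    std::vector<int> c0, c1;
    for (size_t a = 0; a < C.size(); ++a)
      (side[a] ? c1 : c0).push_back(C[a]);
    for (int u : c1) memb[u] = next_label;
    ++next_label;
    queue.push_back(c0);
    queue.push_back(c1);
  }
  relabel(memb);
  return memb;
}

List max_modularity_impl(NumericMatrix A, bool directed) {
  int n = A.nrow();
  QProblem qp;
  qp.n = n;
  qp.B.assign((size_t)n * n, 0.0);
  double m_edges = 0.0;
  for (double v : A) m_edges += v;
  if (m_edges == 0.0) stop("modularity is undefined for a graph with no edges");
  std::vector<double> kout(n, 0.0), kin(n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      kout[i] += A(i, j);
      kin[j] += A(i, j);
    }
  if (directed) {
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        qp.B[i + (size_t)j * n] = A(i, j) / m_edges -
          kout[i] * kin[j] / (m_edges * m_edges);
  } else {
    double two_m = 2.0 * m_edges;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double as = A(i, j) + A(j, i);
        double k_i = kout[i] + kin[i], k_j = kout[j] + kin[j];
        qp.B[i + (size_t)j * n] = as / two_m - k_i * k_j / (two_m * two_m);
      }
  }
  qp.S.assign((size_t)n * n, 0.0);
  qp.diag_sum = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      qp.S[i + (size_t)j * n] = qp.B[i + (size_t)j * n] +
        qp.B[j + (size_t)i * n];
  for (int i = 0; i < n; ++i) qp.diag_sum += qp.B[i + (size_t)i * n];

  auto polish = [&](std::vector<int> memb) {
    double q = q_quality(qp, memb);
    for (;;) {
      q_kl_refine(qp, memb);
      q_merge_phase(qp, memb);
      double q2 = q_quality(qp, memb);
      if (q2 <= q + 1e-12) break;
      q = q2;
    }
    return std::make_pair(memb, q_quality(qp, memb));
  };

  std::vector<int> singletons(n);
  std::iota(singletons.begin(), singletons.end(), 0);
  auto c1 = polish(q_greedy_agglomerate(qp));
  auto c2 = polish(singletons);
  auto c3 = polish(q_bisection_init(qp));
  auto best = c1;
  if (c2.second > best.second) best = c2;
  if (c3.second > best.second) best = c3;
  std::vector<int> memb = best.first;
  relabel(memb);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = memb[i] + 1;
  return List::create(_["q"] = best.second, _["membership"] = out);
}

}  // namespace

// [[Rcpp::export(name = ".engine_max_modularity")]]
List engine_max_modularity(NumericMatrix A, bool directed) {
  return max_modularity_impl(A, directed);
}

// [[Rcpp::export(name = ".engine_mutate_batch")]]
List engine_mutate_batch(List genomes, List params, List problem) {
  Problem pb;
  pb.layers = as<std::vector<int>>(problem["layers"]);
  Params pr;
  pr.r_add = as<double>(params["r_add"]);
  pr.r_remove = as<double>(params["r_remove"]);
  pr.r_thresh = as<double>(params["r_thresh"]);
  pr.r_weight = as<double>(params["r_weight"]);
  pr.real_mode = as<int>(params["real_mode"]);
  pr.sigma = as<double>(params["sigma"]);
  List out(genomes.size());
  for (int i = 0; i < genomes.size(); ++i) {
    Genome g = genome_from_r(as<List>(genomes[i]));
    mutate_genome(g, pb, pr);
    out[i] = genome_to_r(g, pb.layers, pr.real_mode);
  }
  return out;
}

// [[Rcpp::export(name = ".engine_rank_crowd")]]
List engine_rank_crowd(NumericVector perf, SEXP sec, double p) {
  std::vector<double> pv(perf.begin(), perf.end());
  std::vector<double> sv;
  if (!Rf_isNull(sec)) {
    NumericVector s(sec);
    sv.assign(s.begin(), s.end());
  }
  std::vector<int> rank = stoch_sort(pv, sv, p);
  std::vector<double> crowd = crowding(pv, sv, rank);
  return List::create(_["rank"] = wrap(rank), _["crowd"] = wrap(crowd));
}

// [[Rcpp::export(name = ".engine_measure")]]
NumericMatrix engine_measure(List genomes, List problem, int cost_kind) {
  // rows: cost, q, performance; cost_kind 0 = length_sq, 1 = count
  Problem pb;
  pb.layers = as<std::vector<int>>(problem["layers"]);
  NumericMatrix X = as<NumericMatrix>(problem["X"]);
  pb.X.assign(X.begin(), X.end());
  pb.npat = X.nrow();
  List tg = problem["targets"];
  NumericMatrix t0 = as<NumericMatrix>(tg[0]);
  pb.targets.push_back(std::vector<double>(t0.begin(), t0.end()));
  pb.nout = t0.ncol();
  pb.fixed_x = as<std::vector<double>>(problem["fixed_x"]);
  pb.fixed_y = as<std::vector<double>>(problem["fixed_y"]);
  pb.lambda = as<double>(problem["lambda"]);
  pb.bias_sign = as<double>(problem["bias_sign"]);

  int L = pb.layers.size();
  int N = 0;
  for (int s : pb.layers) N += s;
  NumericMatrix out(3, genomes.size());
  for (int gi = 0; gi < genomes.size(); ++gi) {
    Genome g = genome_from_r(as<List>(genomes[gi]));
    double cost = cost_kind == 0 ? placement_cost(g, pb)
                                 : (double)count_connections(g);
    // displayed adjacency for modularity
    std::vector<int> off(L, 0);
    int acc = 0;
    for (int l = 0; l < L; ++l) { off[l] = acc; acc += pb.layers[l]; }
    std::vector<int> deg(N, 0);
    for (int l = 0; l < L - 1; ++l) {
      int a = pb.layers[l], bsz = pb.layers[l + 1];
      for (int j = 0; j < bsz; ++j)
        for (int i = 0; i < a; ++i)
          if (g.W[l][i + (size_t)j * a] != 0.0) {
            ++deg[off[l] + i];
            ++deg[off[l + 1] + j];
          }
    }
    std::vector<int> keep;
    std::vector<int> kid(N, -1);
    for (int i = 0; i < N; ++i)
      if (deg[i] > 0) { kid[i] = keep.size(); keep.push_back(i); }
    double q = 0.0;
    if (!keep.empty()) {
      NumericMatrix A(keep.size(), keep.size());
      for (int l = 0; l < L - 1; ++l) {
        int a = pb.layers[l], bsz = pb.layers[l + 1];
        for (int j = 0; j < bsz; ++j)
          for (int i = 0; i < a; ++i)
            if (g.W[l][i + (size_t)j * a] != 0.0)
              A(kid[off[l] + i], kid[off[l + 1] + j]) = 1.0;
      }
      List mm = max_modularity_impl(A, true);
      q = as<double>(mm["q"]);
    }
    out(0, gi) = cost;
    out(1, gi) = q;
    out(2, gi) = eval_performance(g, pb, 0);
  }
  return out;
}

// [[Rcpp::export(name = ".engine_eval_performance")]]
double engine_eval_performance(List genome, NumericMatrix X,
                               NumericMatrix targets, double lambda,
                               double bias_sign) {
  Problem pb;
  pb.layers = as<std::vector<int>>(genome["layers"]);
  pb.X.assign(X.begin(), X.end());
  pb.npat = X.nrow();
  pb.targets.push_back(std::vector<double>(targets.begin(), targets.end()));
  pb.nout = targets.ncol();
  pb.lambda = lambda;
  pb.bias_sign = bias_sign;
  Genome g = genome_from_r(genome);
  return eval_performance(g, pb, 0);
}

// [[Rcpp::export(name = ".engine_placement_cost")]]
double engine_placement_cost(List genome, NumericVector fixed_x,
                             NumericVector fixed_y) {
  Problem pb;
  pb.layers = as<std::vector<int>>(genome["layers"]);
  pb.fixed_x = as<std::vector<double>>(fixed_x);
  pb.fixed_y = as<std::vector<double>>(fixed_y);
  Genome g = genome_from_r(genome);
  return placement_cost(g, pb);
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List problem, List params, List init_genomes) {
  Problem pb;
  pb.layers = as<std::vector<int>>(problem["layers"]);
  NumericMatrix X = as<NumericMatrix>(problem["X"]);
  pb.X.assign(X.begin(), X.end());
  pb.npat = X.nrow();
  List tg = problem["targets"];
  for (int e = 0; e < tg.size(); ++e) {
    NumericMatrix t = as<NumericMatrix>(tg[e]);
    pb.targets.push_back(std::vector<double>(t.begin(), t.end()));
    pb.nout = t.ncol();
  }
  pb.mvg_period = as<int>(problem["mvg_period"]);
  pb.fixed_x = as<std::vector<double>>(problem["fixed_x"]);
  pb.fixed_y = as<std::vector<double>>(problem["fixed_y"]);
  pb.lambda = as<double>(problem["lambda"]);
  pb.bias_sign = as<double>(problem["bias_sign"]);

  Params pr;
  pr.treatment = as<int>(params["treatment"]);
  pr.p_cost = as<double>(params["p_cost"]);
  pr.pop_size = as<int>(params["pop_size"]);
  pr.generations = as<int>(params["generations"]);
  pr.r_add = as<double>(params["r_add"]);
  pr.r_remove = as<double>(params["r_remove"]);
  pr.r_thresh = as<double>(params["r_thresh"]);
  pr.r_weight = as<double>(params["r_weight"]);
  pr.real_mode = as<int>(params["real_mode"]);
  pr.sigma = as<double>(params["sigma"]);
  pr.stop_at = as<double>(params["stop_at"]);
  pr.snap_every = as<int>(params["snap_every"]);

  int mu = pr.pop_size;
  bool two = pr.treatment != 0;

  // initial population
  std::vector<Genome> pop;
  pop.reserve(mu);
  if (init_genomes.size() > 0) {
    for (int i = 0; i < init_genomes.size(); ++i)
      pop.push_back(genome_from_r(as<List>(init_genomes[i])));
    while ((int)pop.size() < mu) pop.push_back(pop[pop.size() % init_genomes.size()]);
  } else {
    int L = pb.layers.size();
    for (int i = 0; i < mu; ++i) {
      Genome g;
      for (int l = 0; l < L - 1; ++l) {
        std::vector<double> w((size_t)pb.layers[l] * pb.layers[l + 1]);
        static const double vals[5] = {0, -2, -1, 1, 2};
        for (auto& v : w) {
          int vi = (int)(unif_rand() * 5.0);
          if (vi > 4) vi = 4;
          v = vals[vi];
        }
        g.W.push_back(std::move(w));
      }
      for (int l = 0; l < L; ++l) {
        std::vector<double> b(pb.layers[l]);
        for (auto& v : b) {
          int vi = (int)(unif_rand() * 5.0);
          if (vi > 4) vi = 4;
          v = vi - 2.0;
        }
        g.b.push_back(std::move(b));
      }
      pop.push_back(std::move(g));
    }
  }

  int env_idx = 0;
  auto secondary = [&](const Genome& g) -> double {
    switch (pr.treatment) {
      case 1: return -placement_cost(g, pb);
      case 2: return -(double)count_connections(g);
      case 3: return unif_rand();
      default: return 0.0;
    }
  };

  std::vector<double> perf(mu), sec;
  if (two) sec.resize(mu);
  for (int i = 0; i < mu; ++i) {
    perf[i] = eval_performance(pop[i], pb, env_idx);
    if (two) sec[i] = secondary(pop[i]);
  }

  std::vector<double> best_perf;
  best_perf.reserve(pr.generations);
  List snapshots;
  CharacterVector snap_names;
  int gens_run = 0;

  for (int gen = 1; gen <= pr.generations; ++gen) {
    if (pb.mvg_period > 0) {
      int e = ((gen - 1) / pb.mvg_period) % 2;
      if (e != env_idx) {
        env_idx = e;
        for (int i = 0; i < mu; ++i)
          perf[i] = eval_performance(pop[i], pb, env_idx);
      }
    }
    std::vector<double> empty;
    std::vector<int> rank = stoch_sort(perf, two ? sec : empty, pr.p_cost);
    std::vector<double> crowd = crowding(perf, two ? sec : empty, rank);

    // binary tournaments -> mu offspring
    std::vector<Genome> off;
    off.reserve(mu);
    std::vector<double> operf(mu), osec;
    if (two) osec.resize(mu);
    for (int k = 0; k < mu; ++k) {
      int i = (int)(unif_rand() * mu); if (i >= mu) i = mu - 1;
      int j = (int)(unif_rand() * mu); if (j >= mu) j = mu - 1;
      double si = two ? sec[i] : 0.0, sj = two ? sec[j] : 0.0;
      bool dij = stoch_dom_pair(perf[i], si, perf[j], sj, two, pr.p_cost);
      bool dji = stoch_dom_pair(perf[j], sj, perf[i], si, two, pr.p_cost);
      int pick;
      if (dij) pick = i;
      else if (dji) pick = j;
      else if (rank[i] != rank[j]) pick = rank[i] < rank[j] ? i : j;
      else if (crowd[i] != crowd[j]) pick = crowd[i] > crowd[j] ? i : j;
      else pick = unif_rand() < 0.5 ? i : j;
      Genome child = pop[pick];
      mutate_genome(child, pb, pr);
      operf[k] = eval_performance(child, pb, env_idx);
      if (two) osec[k] = secondary(child);
      off.push_back(std::move(child));
    }

    // (mu + lambda) survivor selection under a fresh stochastic sort
    std::vector<double> mperf(perf);
    mperf.insert(mperf.end(), operf.begin(), operf.end());
    std::vector<double> msec;
    if (two) {
      msec = sec;
      msec.insert(msec.end(), osec.begin(), osec.end());
    }
    std::vector<int> mrank = stoch_sort(mperf, two ? msec : empty,
                                        pr.p_cost);
    std::vector<double> mcrowd = crowding(mperf, two ? msec : empty, mrank);
    std::vector<int> ord(2 * mu);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (mrank[a] != mrank[b]) return mrank[a] < mrank[b];
      return mcrowd[a] > mcrowd[b];
    });
    std::vector<Genome> npop;
    npop.reserve(mu);
    std::vector<double> nperf(mu), nsec;
    if (two) nsec.resize(mu);
    for (int k = 0; k < mu; ++k) {
      int idx = ord[k];
      npop.push_back(idx < mu ? std::move(pop[idx])
                              : std::move(off[idx - mu]));
      nperf[k] = mperf[idx];
      if (two) nsec[k] = msec[idx];
    }
    pop.swap(npop);
    perf.swap(nperf);
    if (two) sec.swap(nsec);

    double bp = *std::max_element(perf.begin(), perf.end());
    best_perf.push_back(bp);
    gens_run = gen;
    if (pr.snap_every > 0 && gen % pr.snap_every == 0) {
      int bi = std::max_element(perf.begin(), perf.end()) - perf.begin();
      snapshots.push_back(genome_to_r(pop[bi], pb.layers, pr.real_mode));
      snap_names.push_back(std::to_string(gen));
    }
    if (bp >= pr.stop_at) break;
    if (gen % 256 == 0) Rcpp::checkUserInterrupt();
  }

  if (snapshots.size() > 0) snapshots.attr("names") = snap_names;
  List rpop(mu);
  for (int i = 0; i < mu; ++i)
    rpop[i] = genome_to_r(pop[i], pb.layers, pr.real_mode);
  return List::create(
    _["best_perf"] = wrap(best_perf),
    _["gens_run"] = gens_run,
    _["genomes"] = rpop,
    _["perf"] = wrap(perf),
    _["sec"] = two ? wrap(sec) : R_NilValue,
    _["snapshots"] = snapshots);
}
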