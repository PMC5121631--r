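// Simulated-annealing maximisation of network modularity
//   M = sum_s [ l_s / L - (d_s / 2L)^2 ]
// over joint partitions of the nodes of a bipartite incidence graph,
// plus a degree-preserving checkerboard randomiser for binary matrices.
//
// A private xorshift-free mt19937 stream (raw 32-bit draws, modulo /
// division mapping) keeps results bit-reproducible for a given seed
// independent of the standard library's distribution implementations.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // integer in [0, n)
  int pick(int n) { return static_cast<int>(gen() % static_cast<uint32_t>(n)); }
  double runif() {
    return (static_cast<double>(gen()) + 0.5) / 4294967296.0;
  }
};

struct State {
  int n;                      // nodes
  double L;                   // links
  const std::vector<std::vector<int>>& adj;
  const std::vector<int>& deg;
  std::vector<int> mem;       // node -> module
  std::vector<double> l, d;   // per-module internal links / degree sums
  std::vector<int> sz;        // per-module node count
  std::vector<std::vector<int>> members;  // node lists per module
  std::vector<int> pos;       // node's index within its module list
  std::vector<int> nonempty;  // list of non-empty module ids
  std::vector<int> where;     // module id -> index in nonempty (-1 if empty)
  double M;

  State(int n_, double L_, const std::vector<std::vector<int>>& adj_,
        const std::vector<int>& deg_)
      : n(n_), L(L_), adj(adj_), deg(deg_), mem(n_), l(n_, 0.0), d(n_, 0.0),
        sz(n_, 0), members(n_), pos(n_), where(n_, -1) {
    for (int v = 0; v < n; ++v) {
      mem[v] = v;
      d[v] = deg[v];
      sz[v] = 1;
      members[v].push_back(v);
      pos[v] = 0;
      where[v] = (int)nonempty.size();
      nonempty.push_back(v);
    }
    recompute_M();
  }

  void recompute_M() {
    M = 0.0;
    for (int s : nonempty)
      M += l[s] / L - (d[s] / (2.0 * L)) * (d[s] / (2.0 * L));
  }

  int links_to(int v, int s) const {
    int k = 0;
    for (int u : adj[v]) if (mem[u] == s) ++k;
    return k;
  }

  double delta_single(int v, int b, int& kva, int& kvb) const {
    int a = mem[v];
    kva = links_to(v, a);
    kvb = links_to(v, b);
    double dv = deg[v];
    double da = d[a], db = d[b];
    return (kvb - kva) / L -
           ((da - dv) * (da - dv) + (db + dv) * (db + dv) - da * da - db * db) /
               (4.0 * L * L);
  }

  void detach(int v) {
    int a = mem[v];
    std::vector<int>& ma = members[a];
    int p = pos[v];
    ma[p] = ma.back();
    pos[ma[p]] = p;
    ma.pop_back();
    if (--sz[a] == 0) {
      int idx = where[a];
      nonempty[idx] = nonempty.back();
      where[nonempty[idx]] = idx;
      nonempty.pop_back();
      where[a] = -1;
    }
  }

  void attach(int v, int b) {
    mem[v] = b;
    pos[v] = (int)members[b].size();
    members[b].push_back(v);
    if (sz[b]++ == 0) {
      where[b] = (int)nonempty.size();
      nonempty.push_back(b);
    }
  }

  void move_single(int v, int b, int kva, int kvb) {
    int a = mem[v];
    l[a] -= kva; l[b] += kvb;
    d[a] -= deg[v]; d[b] += deg[v];
    detach(v);
    attach(v, b);
  }

  int find_empty() const {
    for (int s = 0; s < n; ++s) if (sz[s] == 0) return s;
    return -1;  // unreachable: n modules suffice for n nodes
  }

  int edges_between(int a, int b) const {
    int small = (sz[a] <= sz[b]) ? a : b;
    int other = (small == a) ? b : a;
    int e = 0;
    for (int v : members[small])
      for (int u : adj[v]) if (mem[u] == other) ++e;
    return e;
  }

  double delta_merge(int a, int b, int& eab) const {
    eab = edges_between(a, b);
    return eab / L - (2.0 * d[a] * d[b]) / (4.0 * L * L);
  }

  void do_merge(int a, int b, int eab) {
    // move all nodes of b into a
    std::vector<int> nodes = members[b];
    for (int v : nodes) { detach(v); attach(v, a); }
    l[a] += l[b] + eab;
    d[a] += d[b];
    l[b] = 0.0; d[b] = 0.0;
  }
};

double full_M(const State& st) {
  double M = 0.0;
  for (int s : st.nonempty)
    M += st.l[s] / st.L - (st.d[s] / (2.0 * st.L)) * (st.d[s] / (2.0 * st.L));
  return M;
}

// Greedy polish: single-node best moves, then pairwise merges, until stable.
void polish(State& st) {
  bool improved = true;
  while (improved) {
    improved = false;
    for (int v = 0; v < st.n; ++v) {
      // candidate targets: modules of neighbours + one empty module
      double best_delta = 1e-12;
      int best_b = -1, best_kva = 0, best_kvb = 0;
      std::vector<int> cand;
      for (int u : st.adj[v]) cand.push_back(st.mem[u]);
      if (st.sz[st.mem[v]] > 1) {
        int e = st.find_empty();
        if (e >= 0) cand.push_back(e);
      }
      for (int b : cand) {
        if (b == st.mem[v]) continue;
        int kva, kvb;
        double dl = st.delta_single(v, b, kva, kvb);
        if (dl > best_delta) {
          best_delta = dl; best_b = b; best_kva = kva; best_kvb = kvb;
        }
      }
      if (best_b >= 0) {
        st.move_single(v, best_b, best_kva, best_kvb);
        st.M += best_delta;
        improved = true;
      }
    }
    // merge phase; zero-delta merges accepted so ties resolve to the
    // partition with fewest modules (e.g. one module for complete graphs)
    bool merged = true;
    while (merged) {
      merged = false;
      double best_delta = -1e-12;
      int best_a = -1, best_b = -1, best_e = 0;
      for (size_t i = 0; i < st.nonempty.size(); ++i)
        for (size_t j = i + 1; j < st.nonempty.size(); ++j) {
          int a = st.nonempty[i], b = st.nonempty[j], eab;
          double dl = st.delta_merge(a, b, eab);
          if (dl > best_delta) {
            best_delta = dl; best_a = a; best_b = b; best_e = eab;
          }
        }
      if (best_a >= 0) {
        st.do_merge(best_a, best_b, best_e);
        st.M += best_delta;
        merged = true;
        improved = true;
      }
    }
  }
  st.recompute_M();
}

}  // namespace

// [[Rcpp::export]]
List sa_detect_cpp(IntegerVector edge_i, IntegerVector edge_j, int n_nodes,
                   IntegerVector degrees, double t0, double cooling,
                   double move_factor, int patience, double t_min,
                   int max_temps, int seed) {
  int L = edge_i.size();
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < L; ++e) {
    adj[edge_i[e]].push_back(edge_j[e]);
    adj[edge_j[e]].push_back(edge_i[e]);
  }
  std::vector<int> deg(degrees.begin(), degrees.end());
  State st(n_nodes, (double)L, adj, deg);
  Rng rng((uint32_t)seed);

  // auto temperature: scale to typical worsening move from the initial state
  if (t0 <= 0.0) {
    double acc = 0.0; int cnt = 0;
    for (int t = 0; t < 200; ++t) {
      int v = rng.pick(n_nodes);
      int b = st.nonempty[rng.pick((int)st.nonempty.size())];
      if (b == st.mem[v]) continue;
      int kva, kvb;
      double dl = st.delta_single(v, b, kva, kvb);
      if (dl < 0) { acc += -dl; ++cnt; }
    }
    double mean_neg = (cnt > 0) ? acc / cnt : 1.0 / L;
    t0 = mean_neg / 0.030459207;  // -log(0.97)
  }

  std::vector<int> best_mem = st.mem;
  double best_M = st.M;
  int n_single = std::max(1, (int)std::lround(move_factor * n_nodes * n_nodes));
  int n_coll = std::max(1, (int)std::lround(move_factor * n_nodes));
  double T = t0;
  int stale = 0;

  for (int temp = 0; temp < max_temps && T > t_min; ++temp) {
    double best_before = best_M;
    int proposed = 0, accepted = 0;
    for (int it = 0; it < n_single; ++it) {
      int v = rng.pick(n_nodes);
      int b;
      // small chance of proposing a fresh module
      if (rng.runif() < 0.1 && st.sz[st.mem[v]] > 1) b = st.find_empty();
      else b = st.nonempty[rng.pick((int)st.nonempty.size())];
      if (b < 0 || b == st.mem[v]) continue;
      int kva, kvb;
      double dl = st.delta_single(v, b, kva, kvb);
      ++proposed;
      if (dl >= 0 || rng.runif() < std::exp(dl / T)) {
        ++accepted;
        st.move_single(v, b, kva, kvb);
        st.M += dl;
        if (st.M > best_M) { best_M = st.M; best_mem = st.mem; }
      }
    }
    for (int it = 0; it < n_coll; ++it) {
      if (rng.runif() < 0.5) {
        // merge two random modules
        if (st.nonempty.size() < 2) continue;
        int ia = rng.pick((int)st.nonempty.size());
        int ib = rng.pick((int)st.nonempty.size());
        if (ia == ib) continue;
        int a = st.nonempty[ia], b = st.nonempty[ib], eab;
        double dl = st.delta_merge(a, b, eab);
        if (dl >= 0 || rng.runif() < std::exp(dl / T)) {
          st.do_merge(a, b, eab);
          st.M += dl;
          if (st.M > best_M) { best_M = st.M; best_mem = st.mem; }
        }
      } else {
        // random bipartition of one module
        int s = st.nonempty[rng.pick((int)st.nonempty.size())];
        if (st.sz[s] < 2) continue;
        std::vector<int> movers;
        for (int v : st.members[s])
          if (rng.runif() < 0.5) movers.push_back(v);
        if (movers.empty() || (int)movers.size() == st.sz[s]) continue;
        int e = st.find_empty();
        if (e < 0) continue;
        // delta = sum of sequential single-move deltas; evaluate by doing,
        // rolling back if rejected
        double dl_total = 0.0;
        for (int v : movers) {
          int kva, kvb;
          double dl = st.delta_single(v, e, kva, kvb);
          st.move_single(v, e, kva, kvb);
          dl_total += dl;
        }
        if (dl_total >= 0 || rng.runif() < std::exp(dl_total / T)) {
          st.M += dl_total;
          if (st.M > best_M) { best_M = st.M; best_mem = st.mem; }
        } else {
          for (auto it2 = movers.rbegin(); it2 != movers.rend(); ++it2) {
            int kva, kvb;
            st.delta_single(*it2, s, kva, kvb);
            st.move_single(*it2, s, kva, kvb);
          }
        }
      }
    }
    // stop only once the system is frozen: low acceptance and no
    // improvement of the best partition for `patience` temperatures
    double acc_rate = (proposed > 0) ? (double)accepted / proposed : 0.0;
    if (acc_rate < 0.25 && best_M - best_before < 1e-10) {
      if (++stale >= patience) break;
    } else {
      stale = 0;
    }
    T *= cooling;
  }

  // restart from the best partition seen and polish greedily
  State fin(n_nodes, (double)L, adj, deg);
  for (int v = 0; v < n_nodes; ++v) {
    if (fin.mem[v] != best_mem[v]) {
      int kva, kvb;
      fin.delta_single(v, best_mem[v], kva, kvb);
      fin.move_single(v, best_mem[v], kva, kvb);
    }
  }
  fin.recompute_M();
  polish(fin);

  return List::create(Named("membership") = IntegerVector(fin.mem.begin(),
                                                          fin.mem.end()),
                      Named("M") = fin.M);
}

// Degree-preserving randomisation of a binary matrix by checkerboard
// trial swaps: a uniformly chosen row pair / column pair is swapped only
// when its 2x2 submatrix is a checkerboard, giving a symmetric chain whose
// stationary distribution is uniform over all matrices with the observed
// margins.
// [[Rcpp::export]]
List checkerboard_swap_cpp(IntegerMatrix m, int n_trials, int seed) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  Rng rng((uint32_t)seed);
  int successes = 0;
  for (int t = 0; t < n_trials; ++t) {
    int r1 = rng.pick(nr), r2 = rng.pick(nr);
    int c1 = rng.pick(nc), c2 = rng.pick(nc);
    if (r1 == r2 || c1 == c2) continue;
    int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == d && b == c && a != b) {
      out(r1, c1) = b; out(r1, c2) = a;
      out(r2, c1) = d; out(r2, c2) = c;
      ++successes;
    }
  }
  return List::create(Named("matrix") = out,
                      Named("n_successful") = successes);
}
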