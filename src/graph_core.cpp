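// Compute core for binary-graph metrics on thresholded covariance networks.
// All graphs are small (n = 68 in the intended use), undirected, unweighted,
// without self-loops.  Everything here is deterministic: randomized routines
// (edge rewiring, modularity restarts) take an explicit integer seed and use
// a local xorshift generator, so results do not depend on R's RNG state or
// on evaluation order.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// local RNG (xorshift64* seeded through splitmix64)

struct Xrng {
  uint64_t s;
  explicit Xrng(uint64_t seed) {
    // splitmix64 scrambling so that small / similar seeds decorrelate
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, k)
  int below(int k) { return (int)(unif() * k) % k; }
};

// ---------------------------------------------------------------------------
// graph container

struct Graph {
  int n;
  std::vector<std::pair<int,int> > edges;   // 0-based, i < j
  std::vector<std::vector<int> > adj;
  std::vector<uint8_t> amat;                // n*n adjacency lookup

  Graph(int n_) : n(n_), adj(n_), amat((size_t)n_ * n_, 0) {}

  void add_edge(int i, int j) {
    if (i > j) std::swap(i, j);
    edges.push_back(std::make_pair(i, j));
    adj[i].push_back(j);
    adj[j].push_back(i);
    amat[(size_t)i * n + j] = amat[(size_t)j * n + i] = 1;
  }
  bool has(int i, int j) const { return amat[(size_t)i * n + j] != 0; }
  int m() const { return (int)edges.size(); }
};

static Graph graph_from_edges(int n, const IntegerMatrix& edges) {
  Graph g(n);
  for (int e = 0; e < edges.nrow(); ++e)
    g.add_edge(edges(e, 0) - 1, edges(e, 1) - 1);  // 1-based from R
  return g;
}

// ---------------------------------------------------------------------------
// path-based metrics: one sweep of breadth-first searches (Brandes) gives
// per-node mean shortest path length (over reachable nodes), nodal global
// efficiency, and raw betweenness accumulated over ordered pairs.

struct PathMetrics {
  std::vector<double> nlp;      // mean shortest path to reachable nodes; NaN if isolated
  std::vector<double> eglob_i;  // sum_j 1/d_ij / (n-1)
  std::vector<double> bc_raw;   // Brandes accumulation over ordered (s,t) pairs
  std::vector<int>    reach;    // reachable nodes (excluding self)
  bool connected;
};

static void path_metrics(const Graph& g, bool want_bc, PathMetrics& out) {
  const int n = g.n;
  out.nlp.assign(n, std::numeric_limits<double>::quiet_NaN());
  out.eglob_i.assign(n, 0.0);
  out.bc_raw.assign(n, 0.0);
  out.reach.assign(n, 0);
  out.connected = true;

  std::vector<int> dist(n), order; order.reserve(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > preds(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    order.clear();
    if (want_bc) for (int v = 0; v < n; ++v) preds[v].clear();

    dist[s] = 0; sigma[s] = 1.0;
    std::queue<int> q; q.push(s);
    double sumd = 0.0, suminv = 0.0;
    int reach = 0;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      if (v != s) { sumd += dist[v]; suminv += 1.0 / dist[v]; ++reach; }
      for (size_t a = 0; a < g.adj[v].size(); ++a) {
        int w = g.adj[v][a];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          if (want_bc) preds[w].push_back(v);
        }
      }
    }
    out.reach[s] = reach;
    if (reach > 0) out.nlp[s] = sumd / reach;
    if (n > 1) out.eglob_i[s] = suminv / (n - 1);
    if (reach < n - 1) out.connected = false;

    if (want_bc) {
      std::fill(delta.begin(), delta.end(), 0.0);
      for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
        int w = order[idx];
        for (size_t a = 0; a < preds[w].size(); ++a) {
          int v = preds[w][a];
          delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
        }
        if (w != s) out.bc_raw[w] += delta[w];
      }
    }
  }
}

// mean over nodes with at least one reachable partner (characteristic path length)
static double char_path_length(const PathMetrics& pm, int n) {
  double s = 0.0; int k = 0;
  for (int i = 0; i < n; ++i)
    if (pm.reach[i] > 0) { s += pm.nlp[i]; ++k; }
  return k > 0 ? s / k : std::numeric_limits<double>::quiet_NaN();
}

// ---------------------------------------------------------------------------
// clustering: degree, triangle counts, per-node clustering coefficient

struct ClustMetrics {
  std::vector<int>    degree;
  std::vector<double> tri;
  std::vector<double> ci;
};

static void clust_metrics(const Graph& g, ClustMetrics& out) {
  const int n = g.n;
  out.degree.assign(n, 0);
  out.tri.assign(n, 0.0);
  out.ci.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = g.adj[i];
    int k = (int)nb.size();
    out.degree[i] = k;
    if (k < 2) continue;
    int t = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (g.has(nb[a], nb[b])) ++t;
    out.tri[i] = t;
    out.ci[i] = 2.0 * t / ((double)k * (k - 1));
  }
}

static double mean_of(const std::vector<double>& x) {
  double s = 0.0;
  for (size_t i = 0; i < x.size(); ++i) s += x[i];
  return x.empty() ? 0.0 : s / x.size();
}

// ---------------------------------------------------------------------------
// local efficiency: efficiency of the subgraph induced by each node's
// neighbors, normalized by k_i (k_i - 1); 0 when k_i < 2.

static void local_efficiency(const Graph& g, std::vector<double>& eloc) {
  const int n = g.n;
  eloc.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = g.adj[i];
    int k = (int)nb.size();
    if (k < 2) continue;
    // subgraph adjacency among neighbors
    std::vector<std::vector<int> > sub(k);
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (g.has(nb[a], nb[b])) { sub[a].push_back(b); sub[b].push_back(a); }
    // BFS within subgraph from each neighbor; sum 1/d over ordered pairs
    double suminv = 0.0;
    std::vector<int> dist(k);
    for (int s = 0; s < k; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      dist[s] = 0;
      std::queue<int> q; q.push(s);
      while (!q.empty()) {
        int v = q.front(); q.pop();
        if (v != s) suminv += 1.0 / dist[v];
        for (size_t a = 0; a < sub[v].size(); ++a)
          if (dist[sub[v][a]] < 0) { dist[sub[v][a]] = dist[v] + 1; q.push(sub[v][a]); }
      }
    }
    eloc[i] = suminv / ((double)k * (k - 1));
  }
}

// ---------------------------------------------------------------------------
// Newman modularity of a membership vector (0-based labels)

static double modularity_value(const Graph& g, const std::vector<int>& comm) {
  const int m = g.m();
  if (m == 0) return std::numeric_limits<double>::quiet_NaN();
  int K = 0;
  for (size_t i = 0; i < comm.size(); ++i) K = std::max(K, comm[i] + 1);
  std::vector<double> lc(K, 0.0), dc(K, 0.0);
  for (int e = 0; e < m; ++e) {
    int u = comm[g.edges[e].first], v = comm[g.edges[e].second];
    if (u == v) lc[u] += 1.0;
    dc[u] += 1.0; dc[v] += 1.0;
  }
  double q = 0.0;
  for (int c = 0; c < K; ++c) {
    double a = dc[c] / (2.0 * m);
    q += lc[c] / m - a * a;
  }
  return q;
}

// ---------------------------------------------------------------------------
// Louvain-style greedy modularity maximization: repeated local moving with
// community aggregation, randomized node order per restart, best Q kept.

struct WGraph {               // weighted graph for aggregation levels
  int n;
  std::vector<std::vector<std::pair<int,double> > > adj;  // neighbor, weight
  std::vector<double> self;   // 2 * internal weight (loop contribution to degree)
  double two_m;
};

// one sweep-until-convergence of local moving.  If init_singletons, every
// node starts in its own community; otherwise `comm` supplies the starting
// partition (used for the final flat refinement).  Besides the neighboring
// communities, moving a node out into an empty (singleton) community is also
// considered, which lets the optimizer split badly merged communities.
static void local_move(WGraph& g, Xrng& rng, std::vector<int>& comm,
                       bool init_singletons) {
  const int n = g.n;
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = g.self[i];
    for (size_t a = 0; a < g.adj[i].size(); ++a) s += g.adj[i][a].second;
    k[i] = s;
  }
  if (init_singletons) {
    comm.resize(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
  }
  std::vector<double> ktot(n, 0.0);
  std::vector<int> csize(n, 0);
  for (int i = 0; i < n; ++i) { ktot[comm[i]] += k[i]; csize[comm[i]]++; }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);

  std::vector<double> w2c(n, 0.0);
  std::vector<int> touched;
  bool improved = true;
  int guard = 0;
  while (improved && ++guard <= 100) {
    improved = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      touched.clear();
      for (size_t a = 0; a < g.adj[i].size(); ++a) {
        int c = comm[g.adj[i][a].first];
        if (w2c[c] == 0.0) touched.push_back(c);
        w2c[c] += g.adj[i][a].second;
      }
      int old_c = comm[i];
      ktot[old_c] -= k[i];
      csize[old_c]--;
      double best_gain = w2c[old_c] - ktot[old_c] * k[i] / g.two_m;
      int best_c = old_c;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        double gain = w2c[c] - ktot[c] * k[i] / g.two_m;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      // leaving for an empty community has gain 0
      if (csize[old_c] > 0 && 0.0 > best_gain + 1e-12) {
        for (int c = 0; c < n; ++c)
          if (csize[c] == 0) { best_gain = 0.0; best_c = c; break; }
      }
      comm[i] = best_c;
      ktot[best_c] += k[i];
      csize[best_c]++;
      if (best_c != old_c) improved = true;
      for (size_t t = 0; t < touched.size(); ++t) w2c[touched[t]] = 0.0;
      w2c[old_c] = 0.0;
    }
  }
}

static void louvain_level(WGraph& g, Xrng& rng, std::vector<int>& comm) {
  local_move(g, rng, comm, true);
}

static void relabel(std::vector<int>& comm, int& K) {
  std::vector<int> map(comm.size(), -1);
  K = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = K++;
    comm[i] = map[comm[i]];
  }
}

static WGraph aggregate(const WGraph& g, const std::vector<int>& comm, int K) {
  WGraph h;
  h.n = K;
  h.adj.assign(K, std::vector<std::pair<int,double> >());
  h.self.assign(K, 0.0);
  h.two_m = g.two_m;
  std::vector<std::vector<double> > w(K, std::vector<double>(K, 0.0));
  for (int i = 0; i < g.n; ++i) {
    h.self[comm[i]] += g.self[i];
    for (size_t a = 0; a < g.adj[i].size(); ++a) {
      int j = g.adj[i][a].first;
      if (j < i) continue;                    // each undirected edge once
      double wt = g.adj[i][a].second;
      if (comm[i] == comm[j]) h.self[comm[i]] += 2.0 * wt;
      else { w[comm[i]][comm[j]] += wt; w[comm[j]][comm[i]] += wt; }
    }
  }
  for (int u = 0; u < K; ++u)
    for (int v = 0; v < K; ++v)
      if (v != u && w[u][v] > 0.0) h.adj[u].push_back(std::make_pair(v, w[u][v]));
  return h;
}

static void louvain_run(const Graph& g, Xrng& rng, std::vector<int>& best) {
  WGraph w;
  w.n = g.n;
  w.adj.assign(g.n, std::vector<std::pair<int,double> >());
  w.self.assign(g.n, 0.0);
  for (int e = 0; e < g.m(); ++e) {
    int i = g.edges[e].first, j = g.edges[e].second;
    w.adj[i].push_back(std::make_pair(j, 1.0));
    w.adj[j].push_back(std::make_pair(i, 1.0));
  }
  w.two_m = 2.0 * g.m();
  WGraph flat = w;                            // keep the original flat graph

  std::vector<int> node2comm(g.n);
  for (int i = 0; i < g.n; ++i) node2comm[i] = i;

  for (int level = 0; level < 100; ++level) {
    std::vector<int> comm;
    louvain_level(w, rng, comm);
    int K;
    relabel(comm, K);
    for (int i = 0; i < g.n; ++i) node2comm[i] = comm[node2comm[i]];
    if (K == w.n) break;                      // no merge happened: converged
    w = aggregate(w, comm, K);
  }
  // refinement: single-node moves on the flat graph, which can undo merges
  // the aggregated levels locked in
  local_move(flat, rng, node2comm, false);
  int K; relabel(node2comm, K);
  best = node2comm;
}

static void best_partition(const Graph& g, int restarts, uint64_t seed,
                           std::vector<int>& comm, double& q) {
  q = -2.0;
  for (int r = 0; r < restarts; ++r) {
    Xrng rng(seed + 7919ULL * (uint64_t)(r + 1));
    std::vector<int> cand;
    louvain_run(g, rng, cand);
    double qc = modularity_value(g, cand);
    if (qc > q) { q = qc; comm = cand; }
  }
  int K; relabel(comm, K);
}

// ---------------------------------------------------------------------------
// Maslov-Sneppen degree-preserving rewiring (double-edge swaps)

static void rewire_edges(Graph& g, int nswap, Xrng& rng) {
  int m = g.m();
  if (m < 2) return;
  // neighbor lists are not maintained here; callers call rebuild_adj()
  for (int it = 0; it < nswap; ++it) {
    int e1 = rng.below(m), e2 = rng.below(m);
    if (e1 == e2) continue;
    int a = g.edges[e1].first, b = g.edges[e1].second;
    int c = g.edges[e2].first, d = g.edges[e2].second;
    if (rng.unif() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.amat[(size_t)a * g.n + b] = g.amat[(size_t)b * g.n + a] = 0;
    g.amat[(size_t)c * g.n + d] = g.amat[(size_t)d * g.n + c] = 0;
    g.amat[(size_t)a * g.n + d] = g.amat[(size_t)d * g.n + a] = 1;
    g.amat[(size_t)c * g.n + b] = g.amat[(size_t)b * g.n + c] = 1;
    g.edges[e1] = std::make_pair(std::min(a, d), std::max(a, d));
    g.edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
  }
}

static void rebuild_adj(Graph& g) {
  for (int i = 0; i < g.n; ++i) g.adj[i].clear();
  for (int e = 0; e < g.m(); ++e) {
    g.adj[g.edges[e].first].push_back(g.edges[e].second);
    g.adj[g.edges[e].second].push_back(g.edges[e].first);
  }
}

// ---------------------------------------------------------------------------
// exported single-graph routines

// [[Rcpp::export]]
List cpp_shortest_paths(int n, IntegerMatrix edges) {
  Graph g = graph_from_edges(n, edges);
  NumericMatrix d(n, n), sigma(n, n);
  std::vector<int> dist(n);
  std::vector<double> sig(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sig.begin(), sig.end(), 0.0);
    dist[s] = 0; sig[s] = 1.0;
    std::queue<int> q; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t a = 0; a < g.adj[v].size(); ++a) {
        int w = g.adj[v][a];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) sig[w] += sig[v];
      }
    }
    for (int v = 0; v < n; ++v) {
      d(s, v) = dist[v] < 0 ? R_PosInf : (double)dist[v];
      sigma(s, v) = sig[v];
    }
  }
  return List::create(_["d"] = d, _["sigma"] = sigma);
}

// [[Rcpp::export]]
List cpp_graph_metrics(int n, IntegerMatrix edges,
                       bool paths = true, bool bc = true,
                       bool clustering = true, bool eloc = true) {
  Graph g = graph_from_edges(n, edges);
  List out;
  if (clustering || eloc) {
    ClustMetrics cm;
    clust_metrics(g, cm);
    out["degree"] = IntegerVector(cm.degree.begin(), cm.degree.end());
    out["triangles"] = NumericVector(cm.tri.begin(), cm.tri.end());
    out["ci"] = NumericVector(cm.ci.begin(), cm.ci.end());
    out["c_mean"] = mean_of(cm.ci);
  }
  if (paths || bc) {
    PathMetrics pm;
    path_metrics(g, bc, pm);
    out["nlp"] = NumericVector(pm.nlp.begin(), pm.nlp.end());
    out["eglob_i"] = NumericVector(pm.eglob_i.begin(), pm.eglob_i.end());
    out["eglob"] = mean_of(pm.eglob_i);
    out["L"] = char_path_length(pm, n);
    out["reach"] = IntegerVector(pm.reach.begin(), pm.reach.end());
    out["connected"] = pm.connected;
    if (bc) {
      NumericVector b(n);
      double norm = (double)(n - 1) * (n - 2);
      for (int i = 0; i < n; ++i) b[i] = pm.bc_raw[i] / norm;
      out["bc"] = b;
    }
  }
  if (eloc) {
    std::vector<double> el;
    local_efficiency(g, el);
    out["eloc_i"] = NumericVector(el.begin(), el.end());
    out["eloc"] = mean_of(el);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_rewire(int n, IntegerMatrix edges, int nswap, double seed) {
  Graph g = graph_from_edges(n, edges);
  Xrng rng((uint64_t)seed);
  rewire_edges(g, nswap, rng);
  IntegerMatrix out(g.m(), 2);
  for (int e = 0; e < g.m(); ++e) {
    out(e, 0) = g.edges[e].first + 1;
    out(e, 1) = g.edges[e].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_modularity(int n, IntegerMatrix edges, int restarts, double seed) {
  Graph g = graph_from_edges(n, edges);
  std::vector<int> comm;
  double q;
  best_partition(g, restarts, (uint64_t)seed, comm, q);
  int K = 0;
  for (size_t i = 0; i < comm.size(); ++i) K = std::max(K, comm[i] + 1);
  IntegerVector membership(n);
  for (int i = 0; i < n; ++i) membership[i] = comm[i] + 1;
  return List::create(_["membership"] = membership, _["q"] = q,
                      _["n_modules"] = K);
}

// [[Rcpp::export]]
double cpp_modularity_of(int n, IntegerMatrix edges, IntegerVector membership) {
  Graph g = graph_from_edges(n, edges);
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = membership[i] - 1;
  return modularity_value(g, comm);
}

// ---------------------------------------------------------------------------
// batch driver: metric curves over a sparsity grid for a set of correlation
// matrices (one per sliding window).  Edge ranking, nested thresholding, all
// metrics, and the rewired null ensemble run in one call; this is the hot
// path re-executed for every permutation replicate.

struct RankedEdge { double r; int i, j; };

static bool ranked_lt(const RankedEdge& a, const RankedEdge& b) {
  if (a.r != b.r) return a.r > b.r;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

// [[Rcpp::export]]
List cpp_curves(List rmats, NumericVector grid, bool rank_abs,
                bool nodal, bool global_basic, bool community,
                int restarts, int n_null, int swap_factor, double seed) {
  const int W = rmats.size();
  const int T = grid.size();
  if (W == 0) stop("no correlation matrices supplied");
  NumericMatrix r0 = rmats[0];
  const int n = r0.nrow();
  const int M = n * (n - 1) / 2;

  IntegerVector ecount(T);
  for (int t = 0; t < T; ++t) {
    ecount[t] = (int)std::floor(grid[t] * M + 0.5);   // round half up
    if (ecount[t] < 1) stop("sparsity %f yields an empty graph", grid[t]);
    if (ecount[t] > M) stop("sparsity %f exceeds 1", grid[t]);
    if (t > 0 && ecount[t] < ecount[t - 1]) stop("grid must be ascending");
  }

  NumericVector nlp_arr, bc_arr;
  if (nodal) {
    nlp_arr = NumericVector(Dimension(n, T, W));
    bc_arr = NumericVector(Dimension(n, T, W));
  }
  NumericMatrix Cm(T, W), Lm(T, W), Egm(T, W), Elm(T, W), Qm(T, W), Mod(T, W),
                Gam(T, W), Lam(T, W), Sig(T, W);
  LogicalMatrix conn(T, W);

  std::vector<RankedEdge> ranked(M);

  for (int w = 0; w < W; ++w) {
    NumericMatrix r = rmats[w];
    if (r.nrow() != n || r.ncol() != n) stop("matrix %d has wrong dimensions", w + 1);
    int idx = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        ranked[idx].r = rank_abs ? std::fabs(r(i, j)) : r(i, j);
        ranked[idx].i = i; ranked[idx].j = j;
        ++idx;
      }
    std::sort(ranked.begin(), ranked.end(), ranked_lt);

    Graph g(n);
    int added = 0;
    for (int t = 0; t < T; ++t) {
      while (added < ecount[t]) {
        g.add_edge(ranked[added].i, ranked[added].j);
        ++added;
      }
      double Creal = NA_REAL, Lreal = NA_REAL;
      if (global_basic || n_null > 0) {
        ClustMetrics cm;
        clust_metrics(g, cm);
        Creal = mean_of(cm.ci);
      }
      PathMetrics pm;
      if (nodal || global_basic || n_null > 0) {
        path_metrics(g, nodal, pm);
        Lreal = char_path_length(pm, n);
        conn(t, w) = pm.connected;
        if (nodal) {
          double norm = (double)(n - 1) * (n - 2);
          for (int i = 0; i < n; ++i) {
            nlp_arr[i + (size_t)n * (t + (size_t)T * w)] = pm.nlp[i];
            bc_arr[i + (size_t)n * (t + (size_t)T * w)] = pm.bc_raw[i] / norm;
          }
        }
      }
      if (global_basic) {
        Cm(t, w) = Creal;
        Lm(t, w) = Lreal;
        Egm(t, w) = mean_of(pm.eglob_i);
        std::vector<double> el;
        local_efficiency(g, el);
        Elm(t, w) = mean_of(el);
      }
      if (community) {
        std::vector<int> comm;
        double q;
        best_partition(g, restarts,
                       (uint64_t)seed ^ (0xC0FFEEULL + 131ULL * w + 17ULL * t),
                       comm, q);
        int K = 0;
        for (size_t i = 0; i < comm.size(); ++i) K = std::max(K, comm[i] + 1);
        Qm(t, w) = q;
        Mod(t, w) = K;
      }
      if (n_null > 0) {
        double csum = 0.0, lsum = 0.0;
        int lcount = 0;
        Xrng rng((uint64_t)seed ^ (0xABCD1234ULL + 1000003ULL * w + 101ULL * t));
        for (int b = 0; b < n_null; ++b) {
          Graph h = g;                       // surrogates rewire the original
          rewire_edges(h, swap_factor * h.m(), rng);
          rebuild_adj(h);
          ClustMetrics cm2;
          clust_metrics(h, cm2);
          csum += mean_of(cm2.ci);
          PathMetrics pm2;
          path_metrics(h, false, pm2);
          double l2 = char_path_length(pm2, n);
          if (R_finite(l2)) { lsum += l2; ++lcount; }
        }
        double crand = csum / n_null;
        double lrand = lcount > 0 ? lsum / lcount : NA_REAL;
        Gam(t, w) = crand > 0 ? Creal / crand : NA_REAL;
        Lam(t, w) = (R_finite(lrand) && lrand > 0 && R_finite(Lreal))
                      ? Lreal / lrand : NA_REAL;
        Sig(t, w) = (R_finite(Gam(t, w)) && R_finite(Lam(t, w)) && Lam(t, w) != 0)
                      ? Gam(t, w) / Lam(t, w) : NA_REAL;
      }
    }
  }

  List out = List::create(_["edge_counts"] = ecount, _["connected"] = conn);
  if (nodal) { out["Nlp"] = nlp_arr; out["Bc"] = bc_arr; }
  if (global_basic) {
    out["C"] = Cm; out["L"] = Lm; out["Eglob"] = Egm; out["Eloc"] = Elm;
  }
  if (community) { out["Q"] = Qm; out["mod_num"] = Mod; }
  if (n_null > 0) { out["gamma"] = Gam; out["lambda"] = Lam; out["sigma"] = Sig; }
  return out;
}
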