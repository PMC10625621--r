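#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Connected graphlets on 2-4 nodes, coded 1..9:
// 1 edge, 2 3-path, 3 triangle, 4 4-path, 5 3-star, 6 4-cycle,
// 7 tailed triangle, 8 diamond, 9 4-clique.

static inline uint64_t pack2(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 21) | static_cast<uint64_t>(b);
}

// adjacency lists plus a dense bit-matrix for O(1) edge tests
struct Graph {
  std::vector<std::vector<int>> adj;
  std::vector<uint64_t> bits;
  size_t n;
  void build(const std::vector<int> &from, const std::vector<int> &to,
             int n_nodes) {
    n = static_cast<size_t>(n_nodes);
    adj.assign(n_nodes, {});
    bits.assign((n * n + 63) / 64, 0);
    for (size_t e = 0; e < from.size(); ++e) {
      adj[from[e]].push_back(to[e]);
      adj[to[e]].push_back(from[e]);
      set_bit(from[e], to[e]);
      set_bit(to[e], from[e]);
    }
  }
  void set_bit(int a, int b) {
    size_t idx = static_cast<size_t>(a) * n + static_cast<size_t>(b);
    bits[idx >> 6] |= (uint64_t(1) << (idx & 63));
  }
  bool has_edge(int a, int b) const {
    size_t idx = static_cast<size_t>(a) * n + static_cast<size_t>(b);
    return (bits[idx >> 6] >> (idx & 63)) & 1;
  }
};

static int classify(const int *s, int k, const Graph &g) {
  if (k == 2) return 1;
  int deg[4] = {0, 0, 0, 0};
  int m = 0;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j)
      if (g.has_edge(s[i], s[j])) { ++m; ++deg[i]; ++deg[j]; }
  int maxd = 0;
  for (int i = 0; i < k; ++i) if (deg[i] > maxd) maxd = deg[i];
  if (k == 3) return (m == 3) ? 3 : 2;
  switch (m) {
    case 3:  return (maxd == 3) ? 5 : 4;
    case 4:  return (maxd == 3) ? 7 : 6;
    case 5:  return 8;
    default: return 9;
  }
}

struct Collector {
  long long n_stream = 0;
  int cap;
  bool collect;
  std::vector<std::array<int, 5>> res; // type, up to 4 nodes (-1 pad)
  void add(const int *s, int k, const Graph &g) {
    std::array<int, 5> row = {classify(s, k, g), -1, -1, -1, -1};
    for (int i = 0; i < k; ++i) row[i + 1] = s[i];
    ++n_stream;
    if (static_cast<long long>(res.size()) < cap) {
      res.push_back(row);
    } else {
      long long j = static_cast<long long>(unif_rand() * n_stream);
      if (j < cap) res[static_cast<size_t>(j)] = row;
    }
  }
};

// ESU-style enumeration: each connected induced subgraph of size 2..4 that
// contains the anchor and only allowed nodes is emitted exactly once.
// allowed(u) handles cross-anchor ownership: a subgraph belongs to its
// smallest seed member.
struct Esu {
  const Graph *g;
  const std::vector<bool> *is_seed;
  int anchor;
  Collector *out;

  bool allowed(int u) const {
    return !((*is_seed)[u] && u < anchor);
  }
  bool adj_to(int u, const int *s, int k) const {
    for (int i = 0; i < k; ++i) if (g->has_edge(u, s[i])) return true;
    return false;
  }
  void extend(int *s, int k, std::vector<int> ext) {
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      s[k] = w;
      out->add(s, k + 1, *g);
      if (k + 1 < 4) {
        std::vector<int> ext2 = ext;
        for (int u : g->adj[w]) {
          if (u == anchor || !allowed(u)) continue;
          bool skip = false;
          for (int i = 0; i <= k; ++i) if (s[i] == u) { skip = true; break; }
          if (skip) continue;
          // exclusive neighborhood: u must not touch S (before adding w)
          if (adj_to(u, s, k)) continue;
          ext2.push_back(u);
        }
        extend(s, k + 1, std::move(ext2));
      }
    }
  }
  void run() {
    std::vector<int> ext;
    for (int u : g->adj[anchor]) if (allowed(u)) ext.push_back(u);
    int s[4];
    s[0] = anchor;
    extend(s, 1, std::move(ext));
  }
};

static void enumerate_all(const Graph &g, const std::vector<int> &seeds,
                          const std::vector<bool> &is_seed, int cap,
                          bool collect, IntegerVector &counts,
                          std::vector<std::array<int, 5>> *all,
                          long long *total_stream) {
  for (int s : seeds) {
    Collector col;
    col.cap = cap;
    col.collect = collect;
    Esu esu{&g, &is_seed, s, &col};
    esu.run();
    *total_stream += col.n_stream;
    for (const auto &row : col.res) {
      ++counts[row[0] - 1];
      if (collect && all) all->push_back(row);
    }
  }
}

// [[Rcpp::export(name = ".cpp_seeded_graphlets")]]
List cpp_seeded_graphlets(IntegerMatrix edges, int n_nodes,
                          IntegerVector seeds, int max_per_seed,
                          bool collect) {
  std::vector<int> from(edges.column(0).begin(), edges.column(0).end());
  std::vector<int> to(edges.column(1).begin(), edges.column(1).end());
  Graph g;
  g.build(from, to, n_nodes);
  std::vector<bool> is_seed(n_nodes, false);
  std::vector<int> sv(seeds.begin(), seeds.end());
  std::sort(sv.begin(), sv.end());
  for (int s : sv) is_seed[s] = true;

  IntegerVector counts(9);
  std::vector<std::array<int, 5>> all;
  long long total = 0;
  enumerate_all(g, sv, is_seed, max_per_seed, collect, counts, &all, &total);

  IntegerMatrix inst(collect ? static_cast<int>(all.size()) : 0, 5);
  if (collect) {
    for (size_t i = 0; i < all.size(); ++i)
      for (int j = 0; j < 5; ++j)
        inst(static_cast<int>(i), j) =
          (j > 0 && all[i][j] == -1) ? NA_INTEGER : all[i][j];
  }
  return List::create(_["counts"] = counts, _["instances"] = inst,
                      _["n_enumerated"] = static_cast<double>(total));
}

static void do_swaps(std::vector<int> &from, std::vector<int> &to,
                     std::unordered_set<uint64_t> &es, int n_attempts) {
  int m = static_cast<int>(from.size());
  for (int it = 0; it < n_attempts; ++it) {
    int i = static_cast<int>(unif_rand() * m);
    int j = static_cast<int>(unif_rand() * m);
    if (i == j) continue;
    int a = from[i], b = to[i];
    int c = from[j], d = to[j];
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == d || c == b) continue;
    uint64_t k1 = pack2(a, d), k2 = pack2(c, b);
    if (k1 == k2 || es.count(k1) || es.count(k2)) continue;
    es.erase(pack2(a, b));
    es.erase(pack2(from[j], to[j]));
    from[i] = a; to[i] = d;
    from[j] = c; to[j] = b;
    es.insert(k1);
    es.insert(k2);
  }
}

// Degree-preserving double-edge swaps; weights stay attached to edge rows
// in R.
// [[Rcpp::export(name = ".cpp_rewire")]]
IntegerMatrix cpp_rewire(IntegerMatrix edges, int n_attempts) {
  int m = edges.nrow();
  IntegerMatrix out = clone(edges);
  if (m < 2) return out;
  std::vector<int> from(out.column(0).begin(), out.column(0).end());
  std::vector<int> to(out.column(1).begin(), out.column(1).end());
  std::unordered_set<uint64_t> es;
  es.reserve(m * 2);
  for (int e = 0; e < m; ++e) es.insert(pack2(from[e], to[e]));
  do_swaps(from, to, es, n_attempts);
  for (int e = 0; e < m; ++e) { out(e, 0) = from[e]; out(e, 1) = to[e]; }
  return out;
}

// Null distribution of seeded graphlet counts: n_rewires independent
// degree-preserving randomizations of the observed graph, each counted
// with the same enumeration as the observed statistic.
// [[Rcpp::export(name = ".cpp_null_graphlet_counts")]]
IntegerMatrix cpp_null_graphlet_counts(IntegerMatrix edges, int n_nodes,
                                       IntegerVector seeds, int n_rewires,
                                       int n_attempts, int max_per_seed) {
  std::vector<int> from0(edges.column(0).begin(), edges.column(0).end());
  std::vector<int> to0(edges.column(1).begin(), edges.column(1).end());
  std::vector<bool> is_seed(n_nodes, false);
  std::vector<int> sv(seeds.begin(), seeds.end());
  std::sort(sv.begin(), sv.end());
  for (int s : sv) is_seed[s] = true;

  IntegerMatrix out(n_rewires, 9);
  for (int r = 0; r < n_rewires; ++r) {
    std::vector<int> from = from0, to = to0;
    std::unordered_set<uint64_t> es;
    es.reserve(from.size() * 2);
    for (size_t e = 0; e < from.size(); ++e) es.insert(pack2(from[e], to[e]));
    do_swaps(from, to, es, n_attempts);
    Graph g;
    g.build(from, to, n_nodes);
    IntegerVector counts(9);
    long long total = 0;
    enumerate_all(g, sv, is_seed, max_per_seed, false, counts, nullptr,
                  &total);
    for (int t = 0; t < 9; ++t) out(r, t) = counts[t];
    Rcpp::checkUserInterrupt();
  }
  return out;
}
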