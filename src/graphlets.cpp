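#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Orbit counting over connected induced subgraphs on 2-5 nodes (ESU
// enumeration + mask lookup). The catalogue (canonical graphlets with
// per-vertex global orbit ids) is supplied from R; lookup tables mapping
// every k-node adjacency bitmask to per-position orbit ids are built here by
// pushing each canonical graphlet through all vertex permutations.

static inline int pair_bit(int i, int j) { // 0-based, i < j
  return j * (j - 1) / 2 + i;
}

struct OrbitLookup {
  // lookup[k][mask * k + pos] = global orbit id, or -1 if mask disconnected
  std::vector<std::vector<int>> lut; // index 0..3 for k = 2..5
  OrbitLookup(const List &graphlets) {
    lut.resize(4);
    for (int k = 2; k <= 5; ++k)
      lut[k - 2].assign((size_t(1) << (k * (k - 1) / 2)) * k, -1);
    for (int gi = 0; gi < graphlets.size(); ++gi) {
      List g = graphlets[gi];
      int k = as<int>(g["n"]);
      IntegerMatrix edges = g["edges"];
      IntegerVector orbit = g["orbit"]; // global ids, 0-based
      std::vector<int> perm(k);
      for (int i = 0; i < k; ++i) perm[i] = i;
      std::vector<int> &L = lut[k - 2];
      do {
        int mask = 0;
        for (int e = 0; e < edges.nrow(); ++e) {
          int a = perm[edges(e, 0) - 1], b = perm[edges(e, 1) - 1];
          mask |= 1 << (a < b ? pair_bit(a, b) : pair_bit(b, a));
        }
        for (int v = 0; v < k; ++v) L[size_t(mask) * k + perm[v]] = orbit[v];
      } while (std::next_permutation(perm.begin(), perm.end()));
    }
  }
};

struct ESUCounter {
  int n, n_orbits;
  const std::vector<std::vector<int>> &adj;
  std::vector<uint64_t> adjbit; // dense bit matrix, rows of n bits
  size_t words;
  const OrbitLookup &lk;
  std::vector<double> counts; // n x n_orbits, row-major per node
  std::vector<char> covered;  // in sub or neighbor of sub
  int sub[5];
  int depth;                          // current |sub|
  std::vector<std::vector<int>> ext_buf, newly_buf; // per-depth scratch

  ESUCounter(int n_, const std::vector<std::vector<int>> &adj_,
             const OrbitLookup &lk_, int n_orbits_)
      : n(n_), n_orbits(n_orbits_), adj(adj_), lk(lk_) {
    words = (n + 63) / 64;
    adjbit.assign(size_t(n) * words, 0);
    for (int v = 0; v < n; ++v)
      for (int u : adj[v]) adjbit[size_t(v) * words + u / 64] |= uint64_t(1) << (u % 64);
    counts.assign(size_t(n) * n_orbits, 0.0);
    covered.assign(n, 0);
    ext_buf.assign(6, std::vector<int>());
    newly_buf.assign(6, std::vector<int>());
    for (auto &b : ext_buf) b.reserve(n);
    for (auto &b : newly_buf) b.reserve(n);
    depth = 0;
  }

  inline bool connected(int a, int b) const {
    return (adjbit[size_t(a) * words + b / 64] >> (b % 64)) & 1;
  }

  inline void record() {
    int k = depth;
    int s[5];
    for (int i = 0; i < k; ++i) { // insertion sort of <= 5 elements
      int x = sub[i], j = i;
      while (j > 0 && s[j - 1] > x) { s[j] = s[j - 1]; --j; }
      s[j] = x;
    }
    int mask = 0;
    for (int j = 1; j < k; ++j)
      for (int i = 0; i < j; ++i)
        if (connected(s[i], s[j])) mask |= 1 << pair_bit(i, j);
    const std::vector<int> &L = lk.lut[k - 2];
    for (int p = 0; p < k; ++p) {
      int o = L[size_t(mask) * k + p];
      if (o >= 0) counts[size_t(s[p]) * n_orbits + o] += 1.0;
    }
  }

  void extend(int root) {
    if (depth >= 2) record();
    if (depth == 5) return;
    std::vector<int> &ext = ext_buf[depth];
    std::vector<int> &newly = newly_buf[depth];
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      // child extension set = remaining ext + exclusive neighbors of w
      std::vector<int> &ext2 = ext_buf[depth + 1];
      ext2.assign(ext.begin(), ext.end());
      newly.clear();
      for (int u : adj[w]) {
        if (u > root && !covered[u]) {
          ext2.push_back(u);
          covered[u] = 1;
          newly.push_back(u);
        }
      }
      sub[depth++] = w;
      extend(root);
      --depth;
      for (int u : newly) covered[u] = 0;
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      sub[0] = v;
      depth = 1;
      covered[v] = 1;
      std::vector<int> &ext = ext_buf[1];
      ext.clear();
      std::vector<int> marked;
      for (int u : adj[v])
        if (u > v) { ext.push_back(u); covered[u] = 1; marked.push_back(u); }
      extend(v);
      covered[v] = 0;
      for (int u : marked) covered[u] = 0;
    }
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_count_orbits(int n, IntegerMatrix edges, List graphlets,
                               int n_orbits) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a == b) continue;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  OrbitLookup lk(graphlets);
  ESUCounter cnt(n, adj, lk, n_orbits);
  cnt.run();
  NumericMatrix out(n, n_orbits);
  for (int v = 0; v < n; ++v)
    for (int o = 0; o < n_orbits; ++o) out(v, o) = cnt.counts[size_t(v) * n_orbits + o];
  return out;
}
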