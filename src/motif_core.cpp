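#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Self-contained counter-free PRNG (splitmix64-seeded xoshiro256**) so that
// per-realization streams are reproducible from (seed, realization index)
// alone, independent of R's global RNG state.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t r = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform integer in [0, n); n is tiny here so modulo bias is negligible,
  // but use rejection sampling anyway to keep the stream exactly uniform
  inline int unif_int(int n) {
    const uint64_t un = (uint64_t)n;
    const uint64_t lim = UINT64_MAX - (UINT64_MAX % un);
    uint64_t v;
    do { v = next(); } while (v >= lim);
    return (int)(v % un);
  }
};

// stream seed for realization r of a run seeded with `seed`
static inline uint64_t stream_seed(double seed, int r) {
  uint64_t x = (uint64_t)seed;
  x ^= 0x9E3779B97F4A7C15ULL * (uint64_t)(r + 1);
  return splitmix64(x);
}

// One run of the degree-preserving edge-switching chain, in place.
// Move: pick two distinct edges (t1,h1), (t2,h2) uniformly; propose
// (t1,h2), (t2,h1); reject if a loop or multi-edge would arise; a proposal
// identical to the current state (h1==h2 or t1==t2) is an accepted no-op.
// Every attempt (including rejections) counts toward `attempts`.
static void run_chain(std::vector<int> &tail, std::vector<int> &head,
                      std::vector<uint8_t> &adj, int n, double attempts,
                      Xoshiro &rng) {
  const int m = (int)tail.size();
  if (m < 2) return;
  for (double a = 0; a < attempts; a += 1.0) {
    int e1 = rng.unif_int(m);
    int e2 = rng.unif_int(m - 1);
    if (e2 >= e1) ++e2;
    const int t1 = tail[e1], h1 = head[e1];
    const int t2 = tail[e2], h2 = head[e2];
    if (t1 == h2 || t2 == h1) continue;          // would create a loop
    if (h1 == h2 || t1 == t2) continue;          // accepted self-transition
    if (adj[t1 * n + h2] || adj[t2 * n + h1]) continue;  // multi-edge
    adj[t1 * n + h1] = 0; adj[t2 * n + h2] = 0;
    adj[t1 * n + h2] = 1; adj[t2 * n + h1] = 1;
    head[e1] = h2; head[e2] = h1;
  }
}

static void load_edges(const IntegerMatrix &edges, int n,
                       std::vector<int> &tail, std::vector<int> &head,
                       std::vector<uint8_t> &adj) {
  const int m = edges.nrow();
  tail.resize(m); head.resize(m);
  adj.assign((size_t)n * n, 0);
  for (int i = 0; i < m; ++i) {
    tail[i] = edges(i, 0) - 1;
    head[i] = edges(i, 1) - 1;
    adj[tail[i] * n + head[i]] = 1;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_run_chain(IntegerMatrix edges, int n, double attempts,
                            double seed, int stream) {
  std::vector<int> tail, head;
  std::vector<uint8_t> adj;
  load_edges(edges, n, tail, head, adj);
  Xoshiro rng(stream_seed(seed, stream));
  run_chain(tail, head, adj, n, attempts, rng);
  const int m = (int)tail.size();
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = tail[i] + 1; out(i, 1) = head[i] + 1; }
  return out;
}

// M independent chains restarted from `edges`; realizations stacked row-wise
// (realization r occupies rows [r*m, (r+1)*m)). Stream r matches
// cpp_run_chain(..., stream = r) exactly.
// [[Rcpp::export]]
IntegerMatrix cpp_ensemble_edges(IntegerMatrix edges, int n, int M,
                                 double attempts, double seed) {
  const int m = edges.nrow();
  IntegerMatrix out(m * M, 2);
  std::vector<int> tail, head;
  std::vector<uint8_t> adj;
  for (int r = 0; r < M; ++r) {
    load_edges(edges, n, tail, head, adj);
    Xoshiro rng(stream_seed(seed, r));
    run_chain(tail, head, adj, n, attempts, rng);
    for (int i = 0; i < m; ++i) {
      out(r * m + i, 0) = tail[i] + 1;
      out(r * m + i, 1) = head[i] + 1;
    }
  }
  return out;
}

// Fused null-occurrence counting: for each of M chain realizations, test each
// candidate induced subnetwork for containment (the induced adjacency pattern
// on the candidate's vertices must equal the candidate's pattern exactly) and
// accumulate per-candidate counts. candV: ncand x k matrix of 1-based vertex
// indices, each row sorted; candMask: pattern bitmask over the k*(k-1) ordered
// vertex pairs in row-major order (i over rows, j over columns, i != j).
// [[Rcpp::export]]
IntegerVector cpp_ensemble_counts(IntegerMatrix edges, int n, int M,
                                  double attempts, double seed,
                                  IntegerMatrix candV, IntegerVector candMask) {
  const int ncand = candV.nrow();
  const int k = candV.ncol();
  IntegerVector counts(ncand);
  std::vector<int> tail, head;
  std::vector<uint8_t> adj;
  for (int r = 0; r < M; ++r) {
    load_edges(edges, n, tail, head, adj);
    Xoshiro rng(stream_seed(seed, r));
    run_chain(tail, head, adj, n, attempts, rng);
    for (int c = 0; c < ncand; ++c) {
      int mask = 0, b = 0;
      for (int i = 0; i < k; ++i) {
        const int vi = candV(c, i) - 1;
        for (int j = 0; j < k; ++j) {
          if (i == j) continue;
          const int vj = candV(c, j) - 1;
          if (adj[vi * n + vj]) mask |= (1 << b);
          ++b;
        }
      }
      if (mask == candMask[c]) ++counts[c];
    }
  }
  return counts;
}

// Number of weakly connected simple digraphs on k distinctly labeled
// vertices, by exhaustive generation over all 2^(k(k-1)) arc subsets.
// [[Rcpp::export]]
double cpp_count_connected_digraphs(int k) {
  const int narcs = k * (k - 1);
  std::vector<int> at(narcs), ah(narcs);
  int b = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) { at[b] = i; ah[b] = j; ++b; }
  const uint64_t total = 1ULL << narcs;
  double count = 0;
  std::vector<int> parent(k);
  for (uint64_t mask = 0; mask < total; ++mask) {
    for (int i = 0; i < k; ++i) parent[i] = i;
    // union-find over the underlying undirected graph
    for (int a = 0; a < narcs; ++a) {
      if (!(mask & (1ULL << a))) continue;
      int x = at[a], y = ah[a];
      while (parent[x] != x) x = parent[x] = parent[parent[x]];
      while (parent[y] != y) y = parent[y] = parent[parent[y]];
      if (x != y) parent[x] = y;
    }
    int roots = 0;
    for (int i = 0; i < k; ++i) if (parent[i] == i) ++roots;
    if (roots == 1) count += 1.0;
  }
  return count;
}
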