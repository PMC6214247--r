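#include <Rcpp.h>
#include <vector>
#include <set>
#include <queue>
#include <cstdlib>
using namespace Rcpp;

// Helpers for degree-preserving null models. Edges are kept as parallel
// integer vectors (0-based endpoints); adjacency is mirrored in a set-based
// structure for O(log d) membership tests. Randomness comes from R's RNG so
// set.seed() on the R side governs reproducibility.

typedef std::vector< std::set<int> > AdjList;

static bool has_edge(const AdjList &adj, int u, int v) {
  return adj[u].find(v) != adj[u].end();
}

static bool is_connected(const AdjList &adj, int n) {
  if (n == 0) return true;
  std::vector<char> seen(n, 0);
  std::queue<int> q;
  q.push(0);
  seen[0] = 1;
  int count = 1;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (std::set<int>::const_iterator it = adj[u].begin(); it != adj[u].end(); ++it) {
      if (!seen[*it]) { seen[*it] = 1; ++count; q.push(*it); }
    }
  }
  return count == n;
}

static int rand_index(int m) {
  // uniform integer in [0, m); rejection-free is fine at this precision
  int k = (int)(unif_rand() * m);
  if (k == m) k = m - 1;
  return k;
}

// Double-edge swaps preserving the degree sequence. Each attempt consumes a
// fixed number of RNG draws (three), so truncating the attempt budget of a
// seeded stream yields a prefix of the same swap sequence.
// [[Rcpp::export]]
IntegerMatrix rewire_degseq_cpp(IntegerMatrix edges, int n_nodes, int n_attempts,
                                bool preserve_connectivity) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  AdjList adj(n_nodes);
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
    adj[ea[i]].insert(eb[i]);
    adj[eb[i]].insert(ea[i]);
  }
  RNGScope scope;
  for (int it = 0; it < n_attempts; ++it) {
    int i = rand_index(m);
    int j = rand_index(m);
    bool flip = unif_rand() < 0.5;
    if (i == j) continue;
    int a = ea[i], b = eb[i];
    int cc = ea[j], dd = eb[j];
    if (flip) { int tmp = cc; cc = dd; dd = tmp; }
    // proposed new edges: (a, cc) and (b, dd)
    if (a == cc || b == dd) continue;
    if (has_edge(adj, a, cc) || has_edge(adj, b, dd)) continue;
    // apply
    adj[a].erase(b); adj[b].erase(a);
    adj[cc].erase(dd); adj[dd].erase(cc);
    adj[a].insert(cc); adj[cc].insert(a);
    adj[b].insert(dd); adj[dd].insert(b);
    if (preserve_connectivity && !is_connected(adj, n_nodes)) {
      // revert
      adj[a].erase(cc); adj[cc].erase(a);
      adj[b].erase(dd); adj[dd].erase(b);
      adj[a].insert(b); adj[b].insert(a);
      adj[cc].insert(dd); adj[dd].insert(cc);
      continue;
    }
    ea[i] = a; eb[i] = cc;
    ea[j] = b; eb[j] = dd;
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return out;
}

// Greedy latticization: double-edge swaps accepted only when they reduce the
// total band distance over edges, pulling adjacency mass toward the diagonal
// while preserving the degree sequence. The band distance wraps around
// (min(|i-j|, n-|i-j|)) so that a ring lattice is a fixed point.
static inline int band_dist(int i, int j, int n) {
  int d = std::abs(i - j);
  return std::min(d, n - d);
}

// [[Rcpp::export]]
IntegerMatrix latticize_cpp(IntegerMatrix edges, int n_nodes, int n_attempts) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  AdjList adj(n_nodes);
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
    adj[ea[i]].insert(eb[i]);
    adj[eb[i]].insert(ea[i]);
  }
  RNGScope scope;
  for (int it = 0; it < n_attempts; ++it) {
    int i = rand_index(m);
    int j = rand_index(m);
    bool flip = unif_rand() < 0.5;
    if (i == j) continue;
    int a = ea[i], b = eb[i];
    int cc = ea[j], dd = eb[j];
    if (flip) { int tmp = cc; cc = dd; dd = tmp; }
    if (a == cc || b == dd) continue;
    if (has_edge(adj, a, cc) || has_edge(adj, b, dd)) continue;
    int cost_old = band_dist(a, b, n_nodes) + band_dist(cc, dd, n_nodes);
    int cost_new = band_dist(a, cc, n_nodes) + band_dist(b, dd, n_nodes);
    if (cost_new >= cost_old) continue;
    adj[a].erase(b); adj[b].erase(a);
    adj[cc].erase(dd); adj[dd].erase(cc);
    adj[a].insert(cc); adj[cc].insert(a);
    adj[b].insert(dd); adj[dd].insert(b);
    ea[i] = a; eb[i] = cc;
    ea[j] = b; eb[j] = dd;
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return out;
}
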