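#include <Rcpp.h>
using namespace Rcpp;

// Floyd-Warshall all-pairs shortest paths on a dense length matrix.
// Input: n x n matrix of direct edge lengths (R_PosInf where no edge,
// 0 diagonal). Returns the completed distance matrix.
// [[Rcpp::export(name = ".fw_distances")]]
NumericMatrix fw_distances(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d = clone(len);
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      double dkj = d(k, j);
      if (!R_FINITE(dkj)) continue;
      for (int i = 0; i < n; ++i) {
        double via = d(i, k) + dkj;
        if (via < d(i, j)) d(i, j) = via;
      }
    }
  }
  return d;
}

// Degree-preserving double-edge swaps on an undirected binary structure.
// `edges` is an m x 2 matrix of 1-based endpoints (i < j). Performs up to
// `max_tries` trials aiming for `target` accepted swaps; uses R's RNG so
// results are reproducible under set.seed(). Returns the rewired edge list.
// [[Rcpp::export(name = ".rewire_edges")]]
IntegerMatrix rewire_edges(IntegerMatrix edges, int n_nodes, int target,
                           int max_tries) {
  int m = edges.nrow();
  IntegerMatrix e = clone(edges);
  // adjacency lookup
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int k = 0; k < m; ++k) {
    int a = e(k, 0) - 1, b = e(k, 1) - 1;
    adj[a * n_nodes + b] = adj[b * n_nodes + a] = 1;
  }
  int accepted = 0, tries = 0;
  while (accepted < target && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int x = e(e1, 0) - 1, y = e(e1, 1) - 1;
    int u = e(e2, 0) - 1, v = e(e2, 1) - 1;
    if (unif_rand() < 0.5) { int t = u; u = v; v = t; }
    if (x == u || x == v || y == u || y == v) continue;
    if (adj[x * n_nodes + v] || adj[u * n_nodes + y]) continue;
    adj[x * n_nodes + y] = adj[y * n_nodes + x] = 0;
    adj[u * n_nodes + v] = adj[v * n_nodes + u] = 0;
    adj[x * n_nodes + v] = adj[v * n_nodes + x] = 1;
    adj[u * n_nodes + y] = adj[y * n_nodes + u] = 1;
    e(e1, 0) = std::min(x, v) + 1; e(e1, 1) = std::max(x, v) + 1;
    e(e2, 0) = std::min(u, y) + 1; e(e2, 1) = std::max(u, y) + 1;
    ++accepted;
  }
  e.attr("accepted") = accepted;
  return e;
}
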