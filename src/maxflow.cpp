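#include <Rcpp.h>
#include <vector>
#include <deque>
#include <limits>

using namespace Rcpp;

// Edmonds-Karp max-flow on a directed arc list. Undirected edges must be
// passed as two antiparallel arcs by the caller. Node ids are 1-based.
// BFS scans adjacency lists in insertion order, so results are
// deterministic for a fixed arc ordering.
//
// Returns flow value and the source-side indicator of the minimum cut
// (reachable set in the final residual graph).
// [[Rcpp::export]]
List maxflow_cpp(int n_nodes, IntegerVector from, IntegerVector to,
                 NumericVector cap, int source, int sink) {
  const int m = from.size();
  if (to.size() != m || cap.size() != m)
    stop("arc vectors must have equal length");
  if (source < 1 || source > n_nodes || sink < 1 || sink > n_nodes)
    stop("terminal id out of range");
  if (source == sink) stop("source and sink coincide");

  // arc storage: each input arc gets a residual partner of capacity 0
  std::vector<int> head(2 * m), nxt(2 * m);
  std::vector<double> res(2 * m);
  std::vector<int> first(n_nodes + 1, -1), last(n_nodes + 1, -1);
  for (int i = 0; i < m; ++i) {
    int u = from[i], v = to[i];
    if (u < 1 || u > n_nodes || v < 1 || v > n_nodes)
      stop("arc endpoint out of range");
    double c = cap[i];
    if (!R_finite(c) || c < 0) stop("capacities must be finite and >= 0");
    int a = 2 * i, b = 2 * i + 1;
    head[a] = v; res[a] = c;
    head[b] = u; res[b] = 0.0;
    nxt[a] = -1; nxt[b] = -1;
    if (first[u] < 0) first[u] = a; else nxt[last[u]] = a;
    last[u] = a;
    if (first[v] < 0) first[v] = b; else nxt[last[v]] = b;
    last[v] = b;
  }

  const double EPS = 1e-12;
  double flow = 0.0;
  std::vector<int> par_arc(n_nodes + 1);
  std::vector<char> seen(n_nodes + 1);

  for (;;) {
    std::fill(seen.begin(), seen.end(), 0);
    std::deque<int> q;
    q.push_back(source);
    seen[source] = 1;
    bool found = false;
    while (!q.empty() && !found) {
      int u = q.front(); q.pop_front();
      for (int a = first[u]; a >= 0; a = nxt[a]) {
        if (res[a] <= EPS) continue;
        int v = head[a];
        if (seen[v]) continue;
        seen[v] = 1;
        par_arc[v] = a;
        if (v == sink) { found = true; break; }
        q.push_back(v);
      }
    }
    if (!found) break;
    // bottleneck along the path
    double aug = std::numeric_limits<double>::infinity();
    for (int v = sink; v != source; ) {
      int a = par_arc[v];
      if (res[a] < aug) aug = res[a];
      v = head[a ^ 1];
    }
    for (int v = sink; v != source; ) {
      int a = par_arc[v];
      res[a] -= aug;
      res[a ^ 1] += aug;
      v = head[a ^ 1];
    }
    flow += aug;
  }

  // min-cut: nodes reachable from source in residual graph
  std::vector<char> side(n_nodes + 1, 0);
  std::deque<int> q;
  q.push_back(source);
  side[source] = 1;
  while (!q.empty()) {
    int u = q.front(); q.pop_front();
    for (int a = first[u]; a >= 0; a = nxt[a]) {
      if (res[a] <= EPS) continue;
      int v = head[a];
      if (!side[v]) { side[v] = 1; q.push_back(v); }
    }
  }

  LogicalVector src_side(n_nodes);
  for (int v = 1; v <= n_nodes; ++v) src_side[v - 1] = side[v] != 0;
  return List::create(_["flow"] = flow, _["source_side"] = src_side);
}
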