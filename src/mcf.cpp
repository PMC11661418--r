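#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact bipartite matching with per-node capacities via successive
// shortest augmenting paths (min-cost flow with Dijkstra + potentials).
//
// Network: source -> A_i (cap capA, cost 0); A_i -> B_j (cap 1, cost
// cost(i,j)); B_j -> sink (cap capB, cost 0).  All arc costs must be
// nonnegative.  Pushing `flow` units selects `flow` (i,j) pairs with
// minimum total cost, each A used <= capA times, each B <= capB times,
// each pair at most once (z binary).  Integrality of min-cost flow
// guarantees a 0/1 solution.

struct Edge {
  int to;      // head node
  int cap;     // residual capacity
  double cost; // cost per unit
  int rev;     // index of reverse edge in graph[to]
};

// [[Rcpp::export]]
Rcpp::IntegerMatrix mcf_match(Rcpp::NumericMatrix cost, int capA, int capB,
                              int flow) {
  const int m = cost.nrow(), n = cost.ncol();
  const int V = m + n + 2;
  const int S = 0, T = m + n + 1; // A: 1..m, B: m+1..m+n

  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      if (cost(i, j) < 0 || !R_finite(cost(i, j)))
        Rcpp::stop("distances must be finite and nonnegative");
  if (flow > m * capA || flow > n * capB)
    Rcpp::stop("infeasible: requested %d pairs exceed capacity", flow);

  std::vector<std::vector<Edge>> g(V);
  auto add_edge = [&](int u, int v, int cap, double c) {
    g[u].push_back({v, cap, c, (int)g[v].size()});
    g[v].push_back({u, 0, -c, (int)g[u].size() - 1});
  };
  for (int i = 0; i < m; ++i) add_edge(S, 1 + i, capA, 0.0);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) add_edge(1 + i, 1 + m + j, 1, cost(i, j));
  for (int j = 0; j < n; ++j) add_edge(1 + m + j, T, capB, 0.0);

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> pot(V, 0.0), dist(V);
  std::vector<int> pv(V), pe(V);
  std::vector<char> done(V);

  int sent = 0;
  while (sent < flow) {
    // dense Dijkstra with reduced costs
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    dist[S] = 0.0;
    for (;;) {
      int u = -1;
      double best = INF;
      for (int v = 0; v < V; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      for (int k = 0; k < (int)g[u].size(); ++k) {
        const Edge &e = g[u][k];
        if (e.cap <= 0) continue;
        double nd = dist[u] + e.cost + pot[u] - pot[e.to];
        if (nd < dist[e.to] - 1e-15) {
          dist[e.to] = nd;
          pv[e.to] = u;
          pe[e.to] = k;
        }
      }
    }
    if (!R_finite(dist[T]))
      Rcpp::stop("infeasible: cannot route %d pairs (max matching %d)",
                 flow, sent);
    for (int v = 0; v < V; ++v)
      if (R_finite(dist[v])) pot[v] += dist[v];
    // augment one unit along the shortest path
    for (int v = T; v != S; v = pv[v]) {
      Edge &e = g[pv[v]][pe[v]];
      e.cap -= 1;
      g[v][e.rev].cap += 1;
    }
    ++sent;
  }

  // read off selected pairs: A->B arcs with used capacity
  std::vector<std::pair<int, int>> pairs;
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < (int)g[1 + i].size(); ++k) {
      const Edge &e = g[1 + i][k];
      if (e.to >= 1 + m && e.to < 1 + m + n && e.cap == 0 && e.cost >= 0)
        pairs.push_back({i + 1, e.to - m});
    }
  Rcpp::IntegerMatrix out(pairs.size(), 2);
  for (int r = 0; r < (int)pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}
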