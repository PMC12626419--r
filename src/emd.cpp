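// Exact uniform-weight optimal transport (Earth Mover's Distance) between
// two point sets, given their pairwise ground-distance matrix.
//
// The transportation problem is solved as an uncapacitated min-cost flow on
// the complete bipartite graph with integer masses (each of the n sources
// carries m units, each of the m sinks absorbs n units, so total flow is
// n*m and per-unit mass is 1/(n*m)), using successive shortest augmenting
// paths with node potentials (Dijkstra on reduced costs). Every
// augmentation saturates a source or a sink, so at most n + m augmentations
// are required.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export(name = ".emd_transport")]]
double emd_transport(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  // reduce masses by gcd(n, m): for equal-size sets this gives unit
  // supplies, so each augmentation saturates a source (n augmentations)
  long long a = n, b = m;
  while (b) { long long t = a % b; a = b; b = t; }
  const long long g = a;
  std::vector<long long> supply(n, (long long)(m / g));
  std::vector<long long> demand(m, (long long)(n / g));
  std::vector<std::vector<long long> > flow(n, std::vector<long long>(m, 0));
  std::vector<double> pu(n, 0.0), pv(m, 0.0);

  long long remaining = (long long)n * (long long)(m / g);
  while (remaining > 0) {
    // Dijkstra over n + m nodes (sources 0..n-1, sinks n..n+m-1)
    std::vector<double> dist(n + m, INF);
    std::vector<int> par(n + m, -1);       // predecessor node
    std::vector<bool> done(n + m, false);
    for (int i = 0; i < n; ++i)
      if (supply[i] > 0) dist[i] = 0.0;

    for (int it = 0; it < n + m; ++it) {
      int u = -1;
      double best = INF;
      for (int v = 0; v < n + m; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      if (u < n) {
        // source -> every sink (forward arc, uncapacitated)
        for (int j = 0; j < m; ++j) {
          if (done[n + j]) continue;
          double rc = cost(u, j) + pu[u] - pv[j];
          if (dist[u] + rc < dist[n + j] - 1e-15) {
            dist[n + j] = dist[u] + rc;
            par[n + j] = u;
          }
        }
      } else {
        // sink -> sources with positive flow (backward arc)
        int j = u - n;
        for (int i = 0; i < n; ++i) {
          if (done[i] || flow[i][j] == 0) continue;
          double rc = -cost(i, j) - pu[i] + pv[j];
          if (dist[u] + rc < dist[i] - 1e-15) {
            dist[i] = dist[u] + rc;
            par[i] = u;
          }
        }
      }
    }

    // closest reachable sink with unmet demand
    int tj = -1;
    double bestd = INF;
    for (int j = 0; j < m; ++j)
      if (demand[j] > 0 && dist[n + j] < bestd) { bestd = dist[n + j]; tj = j; }
    if (tj < 0) stop("internal error: no augmenting path found");

    // update potentials for reached nodes
    for (int i = 0; i < n; ++i) if (dist[i] < INF) pu[i] += dist[i];
    for (int j = 0; j < m; ++j) if (dist[n + j] < INF) pv[j] += dist[n + j];

    // trace path, find bottleneck
    long long bott = demand[tj];
    int node = n + tj;
    while (par[node] >= 0) {
      int p = par[node];
      if (p < n && node >= n) {
        // forward arc: uncapacitated
      } else {
        // backward arc sink(p) ... actually p >= n means arc sink->source
        int i = node, j = p - n;
        if (flow[i][j] < bott) bott = flow[i][j];
      }
      node = p;
    }
    if (node < n && supply[node] < bott) bott = supply[node];

    // apply augmentation
    node = n + tj;
    while (par[node] >= 0) {
      int p = par[node];
      if (p < n) {
        flow[p][node - n] += bott;
      } else {
        flow[node][p - n] -= bott;
      }
      node = p;
    }
    supply[node] -= bott;
    demand[tj] -= bott;
    remaining -= bott;
  }

  double total = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (flow[i][j] > 0) total += (double)flow[i][j] * cost(i, j);
  return total / ((double)n * (double)(m / g));
}
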