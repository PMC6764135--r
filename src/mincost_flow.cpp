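// Exact solver for the mate-allocation transportation problem:
// choose n_matings boar x sow pairs maximizing the summed pair value,
// subject to at most `capacity` sows per boar and at most one boar per sow.
// Solved as min-cost flow (successive shortest augmenting paths with
// Dijkstra and Johnson potentials); the constraint matrix is totally
// unimodular, so the optimum is integral.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct Edge {
  int to;
  int cap;
  double cost;
  int rev; // index of reverse edge in graph[to]
};

typedef std::vector<std::vector<Edge> > Graph;

void add_edge(Graph &g, int from, int to, int cap, double cost) {
  Edge a;
  a.to = to; a.cap = cap; a.cost = cost; a.rev = (int)g[to].size();
  Edge b;
  b.to = from; b.cap = 0; b.cost = -cost; b.rev = (int)g[from].size();
  g[from].push_back(a);
  g[to].push_back(b);
}

} // namespace

// [[Rcpp::export(name = ".mcf_allocate")]]
IntegerMatrix mcf_allocate(NumericMatrix value, int capacity, int n_matings) {
  const int nb = value.nrow(), ns = value.ncol();
  const int S = nb + ns, T = nb + ns + 1, N = nb + ns + 2;

  // maximisation -> nonnegative costs: cost = maxval - value. Total flow is
  // fixed at n_matings, so the constant shift cannot change the argmax.
  double maxval = value(0, 0);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < ns; ++j)
      if (value(i, j) > maxval) maxval = value(i, j);

  Graph g(N);
  for (int i = 0; i < nb; ++i) add_edge(g, S, i, capacity, 0.0);
  for (int j = 0; j < ns; ++j) add_edge(g, nb + j, T, 1, 0.0);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < ns; ++j)
      add_edge(g, i, nb + j, 1, maxval - value(i, j));

  std::vector<double> pot(N, 0.0), dist(N);
  std::vector<int> prev_node(N), prev_edge(N);
  const double INF = std::numeric_limits<double>::infinity();

  int flow = 0;
  while (flow < n_matings) {
    std::fill(dist.begin(), dist.end(), INF);
    dist[S] = 0.0;
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(QE(0.0, S));
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      int v = top.second;
      if (top.first > dist[v] + 1e-12) continue;
      for (int e = 0; e < (int)g[v].size(); ++e) {
        const Edge &ed = g[v][e];
        if (ed.cap <= 0) continue;
        double nd = dist[v] + ed.cost + pot[v] - pot[ed.to];
        if (nd < dist[ed.to] - 1e-12) {
          dist[ed.to] = nd;
          prev_node[ed.to] = v;
          prev_edge[ed.to] = e;
          pq.push(QE(nd, ed.to));
        }
      }
    }
    if (dist[T] == INF) break; // infeasible: caller checks flow < n_matings
    for (int v = 0; v < N; ++v)
      if (dist[v] < INF) pot[v] += dist[v];
    // unit augmentation along the shortest path
    for (int v = T; v != S; v = prev_node[v]) {
      Edge &ed = g[prev_node[v]][prev_edge[v]];
      ed.cap -= 1;
      g[v][ed.rev].cap += 1;
    }
    ++flow;
  }

  // selected pairs = saturated boar->sow edges
  std::vector<std::pair<int, int> > pairs;
  for (int i = 0; i < nb; ++i) {
    for (int e = 0; e < (int)g[i].size(); ++e) {
      const Edge &ed = g[i][e];
      if (ed.to >= nb && ed.to < nb + ns && ed.cap == 0) {
        // forward boar->sow edges have cap 1; cap==0 means selected
        pairs.push_back(std::make_pair(i + 1, ed.to - nb + 1));
      }
    }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (int k = 0; k < (int)pairs.size(); ++k) {
    out(k, 0) = pairs[k].first;
    out(k, 1) = pairs[k].second;
  }
  out.attr("flow") = flow;
  return out;
}
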