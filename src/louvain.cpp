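#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Fisher-Yates shuffle driven by R's RNG so set.seed() controls sweep order.
static void shuffle_order(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj; // neighbor, weight
  std::vector<double> selfw;  // self-loop weight, directed-sum convention
  std::vector<double> k;      // strength incl. self-loop
  double two_m;
};

static Graph build_graph(int n, const std::vector<int> &ei,
                         const std::vector<int> &ej,
                         const std::vector<double> &ew) {
  Graph g;
  g.n = n;
  g.adj.assign(n, std::vector<std::pair<int, double> >());
  g.selfw.assign(n, 0.0);
  g.k.assign(n, 0.0);
  g.two_m = 0.0;
  for (size_t e = 0; e < ei.size(); ++e) {
    int a = ei[e], b = ej[e];
    double w = ew[e];
    if (a == b) {
      g.selfw[a] += 2.0 * w; // A_ii carries both directions
    } else {
      g.adj[a].push_back(std::make_pair(b, w));
      g.adj[b].push_back(std::make_pair(a, w));
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = g.selfw[i];
    for (size_t t = 0; t < g.adj[i].size(); ++t) s += g.adj[i][t].second;
    g.k[i] = s;
    g.two_m += s;
  }
  return g;
}

static double partition_q(const Graph &g, const std::vector<int> &comm,
                          double gamma) {
  int nc = 0;
  for (int i = 0; i < g.n; ++i) nc = std::max(nc, comm[i] + 1);
  std::vector<double> win(nc, 0.0), tot(nc, 0.0);
  for (int i = 0; i < g.n; ++i) {
    tot[comm[i]] += g.k[i];
    win[comm[i]] += g.selfw[i];
    for (size_t t = 0; t < g.adj[i].size(); ++t)
      if (comm[g.adj[i][t].first] == comm[i]) win[comm[i]] += g.adj[i][t].second;
  }
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += win[c] / g.two_m - gamma * (tot[c] / g.two_m) * (tot[c] / g.two_m);
  return q;
}

// One local-moving phase; comm modified in place. Returns true if any move.
static bool local_move(const Graph &g, std::vector<int> &comm, double gamma) {
  std::vector<double> tot(g.n, 0.0);
  for (int i = 0; i < g.n; ++i) tot[comm[i]] += g.k[i];
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;
  shuffle_order(order);
  std::vector<double> wc(g.n, 0.0); // weight to community, sparse-cleared
  bool any_move = false, improved = true;
  while (improved) {
    improved = false;
    for (int oi = 0; oi < g.n; ++oi) {
      int i = order[oi];
      int ci = comm[i];
      std::vector<int> touched;
      touched.push_back(ci);
      for (size_t t = 0; t < g.adj[i].size(); ++t) {
        int c = comm[g.adj[i][t].first];
        if (wc[c] == 0.0 && c != ci) touched.push_back(c);
        wc[c] += g.adj[i][t].second;
      }
      tot[ci] -= g.k[i];
      int best = ci;
      double best_gain = wc[ci] - gamma * g.k[i] * tot[ci] / g.two_m;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double gain = wc[c] - gamma * g.k[i] * tot[c] / g.two_m;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best = c;
        }
      }
      tot[best] += g.k[i];
      if (best != ci) {
        comm[i] = best;
        improved = true;
        any_move = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) wc[touched[t]] = 0.0;
    }
  }
  return any_move;
}

static void relabel(std::vector<int> &comm) {
  std::vector<int> map(comm.size(), -1);
  int nxt = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = nxt++;
    comm[i] = map[comm[i]];
  }
}

// [[Rcpp::export(name = ".louvain_cpp")]]
List louvain_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                 NumericVector edge_w, double gamma) {
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<double> ew(edge_w.begin(), edge_w.end());

  std::vector<int> membership(n);
  for (int i = 0; i < n; ++i) membership[i] = i;

  std::vector<double> q_trace;
  Graph g = build_graph(n, ei, ej, ew);
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;
  // membership maps original node -> current super-node
  std::vector<int> node2super(n);
  for (int i = 0; i < n; ++i) node2super[i] = i;

  for (int level = 0; level < 128; ++level) {
    bool moved = local_move(g, comm, gamma);
    relabel(comm);
    for (int i = 0; i < n; ++i) node2super[i] = comm[node2super[i]];
    q_trace.push_back(partition_q(g, comm, gamma));
    if (!moved) break;
    // aggregate
    int nc = 0;
    for (int i = 0; i < g.n; ++i) nc = std::max(nc, comm[i] + 1);
    std::vector<int> nei, nej;
    std::vector<double> nw;
    // accumulate via map over community pairs
    std::vector<std::vector<std::pair<int, double> > > acc(nc);
    std::vector<double> nself(nc, 0.0);
    for (int i = 0; i < g.n; ++i) {
      nself[comm[i]] += g.selfw[i];
      for (size_t t = 0; t < g.adj[i].size(); ++t) {
        int j = g.adj[i][t].first;
        if (j < i) continue; // each undirected edge once
        int a = comm[i], b = comm[j];
        if (a == b) {
          nself[a] += 2.0 * g.adj[i][t].second;
        } else {
          int lo = std::min(a, b), hi = std::max(a, b);
          bool found = false;
          for (size_t u = 0; u < acc[lo].size(); ++u)
            if (acc[lo][u].first == hi) {
              acc[lo][u].second += g.adj[i][t].second;
              found = true;
              break;
            }
          if (!found) acc[lo].push_back(std::make_pair(hi, g.adj[i][t].second));
        }
      }
    }
    for (int a = 0; a < nc; ++a) {
      if (nself[a] > 0) {
        nei.push_back(a);
        nej.push_back(a);
        nw.push_back(nself[a] / 2.0);
      }
      for (size_t u = 0; u < acc[a].size(); ++u) {
        nei.push_back(a);
        nej.push_back(acc[a][u].first);
        nw.push_back(acc[a][u].second);
      }
    }
    g = build_graph(nc, nei, nej, nw);
    comm.assign(nc, 0);
    for (int i = 0; i < nc; ++i) comm[i] = i;
  }

  std::vector<int> memb(node2super);
  relabel(memb);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = memb[i] + 1; // 1-based labels
  return List::create(_["membership"] = out,
                      _["q"] = q_trace.back(),
                      _["q_trace"] = NumericVector(q_trace.begin(), q_trace.end()));
}

// Degree-preserving double-edge swaps (Maslov-Sneppen); weights follow edges.
// [[Rcpp::export(name = ".rewire_cpp")]]
List rewire_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                NumericVector edge_w, double iters_per_edge) {
  int m = edge_i.size();
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<double> ew(edge_w.begin(), edge_w.end());
  std::unordered_set<int64_t> present;
  present.reserve(m * 2);
  int64_t N = n;
  for (int e = 0; e < m; ++e) {
    int a = std::min(ei[e], ej[e]), b = std::max(ei[e], ej[e]);
    present.insert((int64_t)a * N + b);
  }
  long attempts = (long)std::ceil(iters_per_edge * m);
  long success = 0;
  for (long it = 0; it < attempts; ++it) {
    int e1 = (int)std::floor(unif_rand() * m);
    int e2 = (int)std::floor(unif_rand() * m);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d); // random orientation
    // propose a-d and c-b
    if (a == d || c == b) continue;
    if (a == c || b == d) continue; // shared endpoint: swap is a no-op/loop
    int lo1 = std::min(a, d), hi1 = std::max(a, d);
    int lo2 = std::min(c, b), hi2 = std::max(c, b);
    int64_t k1 = (int64_t)lo1 * N + hi1, k2 = (int64_t)lo2 * N + hi2;
    if (present.count(k1) || present.count(k2)) continue;
    int oa = std::min(ei[e1], ej[e1]), ob = std::max(ei[e1], ej[e1]);
    int oc = std::min(ei[e2], ej[e2]), od = std::max(ei[e2], ej[e2]);
    present.erase((int64_t)oa * N + ob);
    present.erase((int64_t)oc * N + od);
    present.insert(k1);
    present.insert(k2);
    ei[e1] = a; ej[e1] = d;
    ei[e2] = c; ej[e2] = b;
    ++success;
  }
  return List::create(_["edge_i"] = IntegerVector(ei.begin(), ei.end()),
                      _["edge_j"] = IntegerVector(ej.begin(), ej.end()),
                      _["edge_w"] = NumericVector(ew.begin(), ew.end()),
                      _["n_swaps"] = (double)success);
}

// Degree-preserving swaps restricted to between-module edges: within-module
// edges are untouched and proposals that would create a within-module edge
// are rejected, so each node's within-module strength is preserved exactly.
// [[Rcpp::export(name = ".rewire_between_cpp")]]
List rewire_between_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                        NumericVector edge_w, IntegerVector membership,
                        double iters_per_edge) {
  int m = edge_i.size();
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<double> ew(edge_w.begin(), edge_w.end());
  std::vector<int> memb(membership.begin(), membership.end());
  std::vector<int> bet; // indices of between-module edges
  std::unordered_set<int64_t> present;
  present.reserve(m * 2);
  int64_t N = n;
  for (int e = 0; e < m; ++e) {
    int a = std::min(ei[e], ej[e]), b = std::max(ei[e], ej[e]);
    present.insert((int64_t)a * N + b);
    if (memb[ei[e]] != memb[ej[e]]) bet.push_back(e);
  }
  int mb = (int)bet.size();
  long success = 0;
  if (mb >= 2) {
    long attempts = (long)std::ceil(iters_per_edge * mb);
    for (long it = 0; it < attempts; ++it) {
      int x1 = bet[(int)std::floor(unif_rand() * mb)];
      int x2 = bet[(int)std::floor(unif_rand() * mb)];
      if (x1 == x2) continue;
      int a = ei[x1], b = ej[x1], c = ei[x2], d = ej[x2];
      if (unif_rand() < 0.5) std::swap(c, d);
      if (a == d || c == b || a == c || b == d) continue;
      if (memb[a] == memb[d] || memb[c] == memb[b]) continue;
      int lo1 = std::min(a, d), hi1 = std::max(a, d);
      int lo2 = std::min(c, b), hi2 = std::max(c, b);
      int64_t k1 = (int64_t)lo1 * N + hi1, k2 = (int64_t)lo2 * N + hi2;
      if (present.count(k1) || present.count(k2)) continue;
      int oa = std::min(ei[x1], ej[x1]), ob = std::max(ei[x1], ej[x1]);
      int oc = std::min(ei[x2], ej[x2]), od = std::max(ei[x2], ej[x2]);
      present.erase((int64_t)oa * N + ob);
      present.erase((int64_t)oc * N + od);
      present.insert(k1);
      present.insert(k2);
      ei[x1] = a; ej[x1] = d;
      ei[x2] = c; ej[x2] = b;
      ++success;
    }
  }
  return List::create(_["edge_i"] = IntegerVector(ei.begin(), ei.end()),
                      _["edge_j"] = IntegerVector(ej.begin(), ej.end()),
                      _["edge_w"] = NumericVector(ew.begin(), ew.end()),
                      _["n_swaps"] = (double)success);
}
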