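#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Prize-collecting Steiner tree heuristic on an undirected graph with node
// prizes.  Connection costs are folded into node penalties: traversing an
// edge (u,v) costs half of each endpoint's negative prize plus a small
// epsilon, so routes prefer high-prize connectors.  Seeds (prize > 0) are
// merged Takahashi-Matsuyama style (cheapest shortest path to the growing
// tree first), then the optimal connected subtree of the merged tree is
// extracted by dynamic programming ("strong pruning"), which is exact on
// trees.  All tie-breaks use the smallest node index so results are
// bit-reproducible; the caller indexes nodes in lexicographic gene order.

struct PQItem {
  double dist;
  int node;
  bool operator>(const PQItem& other) const {
    if (dist != other.dist) return dist > other.dist;
    return node > other.node;
  }
};

// [[Rcpp::export(name = ".pcst_tm")]]
List pcst_tm(int n, IntegerVector efrom, IntegerVector eto,
             NumericVector prize, double eps = 1e-6) {
  int m = efrom.size();
  std::vector<std::vector<int>> adj(n), adj_eid(n);
  std::vector<double> elen(m);
  std::vector<double> pen(n);
  for (int v = 0; v < n; ++v) pen[v] = prize[v] < 0 ? -prize[v] : 0.0;
  for (int e = 0; e < m; ++e) {
    int u = efrom[e], v = eto[e];
    adj[u].push_back(v); adj_eid[u].push_back(e);
    adj[v].push_back(u); adj_eid[v].push_back(e);
    elen[e] = (pen[u] + pen[v]) / 2.0 + eps;
  }
  // sort adjacency by neighbour index for deterministic traversal
  for (int v = 0; v < n; ++v) {
    std::vector<int> ord(adj[v].size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return adj[v][a] < adj[v][b];
    });
    std::vector<int> na(ord.size()), ne(ord.size());
    for (size_t i = 0; i < ord.size(); ++i) {
      na[i] = adj[v][ord[i]]; ne[i] = adj_eid[v][ord[i]];
    }
    adj[v] = na; adj_eid[v] = ne;
  }

  // connected components
  std::vector<int> comp(n, -1);
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != -1) continue;
    std::vector<int> stack = {s};
    comp[s] = ncomp;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (int u : adj[v]) if (comp[u] == -1) { comp[u] = ncomp; stack.push_back(u); }
    }
    ++ncomp;
  }

  double best_obj = 0.0;
  bool have_best = false;
  std::vector<int> best_nodes;
  std::vector<std::pair<int,int>> best_edges;

  std::vector<char> in_tree(n);
  std::vector<double> dist(n);
  std::vector<int> par(n), par_eid(n);

  for (int c = 0; c < ncomp; ++c) {
    // seeds in this component
    int root = -1;
    double root_prize = 0.0;
    int n_seeds = 0;
    for (int v = 0; v < n; ++v) {
      if (comp[v] == c && prize[v] > 0) {
        ++n_seeds;
        if (root == -1 || prize[v] > root_prize) { root = v; root_prize = prize[v]; }
      }
    }
    if (root == -1) continue;

    std::fill(in_tree.begin(), in_tree.end(), 0);
    in_tree[root] = 1;
    std::vector<int> tree_nodes = {root};
    std::vector<std::pair<int,int>> tree_edges;  // (u,v) pairs
    int attached = 1;

    while (attached < n_seeds) {
      // multi-source Dijkstra from the current tree
      std::fill(dist.begin(), dist.end(), R_PosInf);
      std::fill(par.begin(), par.end(), -1);
      std::priority_queue<PQItem, std::vector<PQItem>, std::greater<PQItem>> pq;
      for (int v : tree_nodes) { dist[v] = 0.0; pq.push({0.0, v}); }
      while (!pq.empty()) {
        PQItem it = pq.top(); pq.pop();
        if (it.dist > dist[it.node]) continue;
        int v = it.node;
        for (size_t i = 0; i < adj[v].size(); ++i) {
          int u = adj[v][i], e = adj_eid[v][i];
          double nd = it.dist + elen[e];
          if (nd < dist[u]) {
            dist[u] = nd; par[u] = v; par_eid[u] = e;
            pq.push({nd, u});
          }
        }
      }
      // cheapest unattached seed; ties -> smallest index
      int pick = -1;
      for (int v = 0; v < n; ++v) {
        if (comp[v] == c && prize[v] > 0 && !in_tree[v] && R_finite(dist[v])) {
          if (pick == -1 || dist[v] < dist[pick]) pick = v;
        }
      }
      if (pick == -1) break;  // remaining seeds unreachable (cannot happen within a component)
      // splice the path from pick back to the tree
      int v = pick;
      while (!in_tree[v]) {
        in_tree[v] = 1;
        tree_nodes.push_back(v);
        tree_edges.push_back({par[v], v});
        v = par[v];
      }
      ++attached;
    }

    // ---- strong pruning: best connected subtree of the merged tree ----
    // build tree adjacency
    std::vector<std::vector<int>> tadj(n);
    for (auto& e : tree_edges) {
      tadj[e.first].push_back(e.second);
      tadj[e.second].push_back(e.first);
    }
    // DFS order from root
    std::vector<int> order; order.reserve(tree_nodes.size());
    std::vector<int> tpar(n, -1);
    {
      std::vector<int> stack = {root};
      std::vector<char> seen(n, 0);
      seen[root] = 1;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        order.push_back(v);
        for (int u : tadj[v]) if (!seen[u]) { seen[u] = 1; tpar[u] = v; stack.push_back(u); }
      }
    }
    std::vector<double> f(n, 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int v = order[i];
      f[v] = prize[v];
      for (int u : tadj[v]) if (tpar[u] == v && f[u] > 0) f[v] += f[u];
    }
    int vstar = -1;
    for (int v : order) if (vstar == -1 || f[v] > f[vstar]) vstar = v;
    // note: ties keep the first in DFS order; re-check smallest index among ties
    for (int v : order) if (f[v] == f[vstar] && v < vstar) vstar = v;

    // extract kept subtree rooted at vstar: descend into children (w.r.t.
    // vstar as root) with positive f-value computed w.r.t. original rooting.
    // Re-root: children of vstar in re-rooted tree are all tadj neighbours
    // except its original parent chain; f values w.r.t. original root are
    // only valid for descendants of vstar, so restrict to the subtree below
    // vstar (which attains f[vstar] by construction).
    std::vector<char> keep(n, 0);
    {
      std::vector<int> stack = {vstar};
      keep[vstar] = 1;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        for (int u : tadj[v]) {
          if (tpar[u] == v && f[u] > 0 && !keep[u]) { keep[u] = 1; stack.push_back(u); }
        }
      }
    }
    double obj = f[vstar];
    std::vector<int> knodes;
    std::vector<std::pair<int,int>> kedges;
    for (int v : tree_nodes) if (keep[v]) knodes.push_back(v);
    for (auto& e : tree_edges)
      if (keep[e.first] && keep[e.second]) kedges.push_back(e);
    std::sort(knodes.begin(), knodes.end());

    if (!have_best || obj > best_obj ||
        (obj == best_obj && !best_nodes.empty() && !knodes.empty() &&
         knodes[0] < best_nodes[0])) {
      have_best = true;
      best_obj = obj;
      best_nodes = knodes;
      best_edges = kedges;
    }
  }

  IntegerVector out_nodes(best_nodes.size());
  for (size_t i = 0; i < best_nodes.size(); ++i) out_nodes[i] = best_nodes[i] + 1;
  IntegerMatrix out_edges(best_edges.size(), 2);
  for (size_t i = 0; i < best_edges.size(); ++i) {
    int a = best_edges[i].first + 1, b = best_edges[i].second + 1;
    out_edges(i, 0) = std::min(a, b);
    out_edges(i, 1) = std::max(a, b);
  }
  return List::create(_["nodes"] = out_nodes,
                      _["edges"] = out_edges,
                      _["objective"] = have_best ? best_obj : 0.0);
}
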