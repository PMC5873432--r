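#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local efficiency of a binary undirected graph: for every node i, the
// global efficiency (mean inverse geodesic distance over ordered pairs,
// disconnected pairs contributing 0) of the subgraph induced by the
// neighbours of i, node i itself excluded; nodes with degree < 2
// contribute 0. Returns the per-node values; the graph-level index is
// their mean over all N nodes.
// [[Rcpp::export]]
NumericVector local_efficiency_nodes_cpp(const LogicalMatrix& adj) {
  const int n = adj.nrow();
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) nbr[i].push_back(j);

  NumericVector eff(n);
  std::vector<int> local(n, -1);

  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = nbr[i];
    const int k = (int) nb.size();
    if (k < 2) { eff[i] = 0.0; continue; }
    for (int a = 0; a < k; ++a) local[nb[a]] = a;

    // induced-subgraph adjacency as bitset rows (and lists for BFS)
    const int w = (k + 63) / 64;
    std::vector<uint64_t> bits((size_t) k * w, 0);
    std::vector< std::vector<int> > sub(k);
    for (int a = 0; a < k; ++a)
      for (size_t t = 0; t < nbr[nb[a]].size(); ++t) {
        int j = nbr[nb[a]][t];
        if (local[j] >= 0) {
          int b = local[j];
          bits[(size_t) a * w + (b >> 6)] |= (uint64_t) 1 << (b & 63);
          sub[a].push_back(b);
        }
      }

    // most pairs resolve at distance 1 (adjacent) or 2 (shared
    // neighbour, via bitset intersection); the rest fall back on BFS
    double inv_sum = 0.0;
    std::vector<int> far_src;
    std::vector<bool> need_bfs(k, false);
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        if (bits[(size_t) a * w + (b >> 6)] & ((uint64_t) 1 << (b & 63))) {
          inv_sum += 2.0;               // ordered pairs, d = 1
          continue;
        }
        bool share = false;
        const uint64_t* ra = &bits[(size_t) a * w];
        const uint64_t* rb = &bits[(size_t) b * w];
        for (int t = 0; t < w; ++t)
          if (ra[t] & rb[t]) { share = true; break; }
        if (share) inv_sum += 1.0;      // ordered pairs, d = 2
        else if (!need_bfs[a]) { need_bfs[a] = true; far_src.push_back(a); }
      }

    if (!far_src.empty()) {
      std::vector<int> dist(k), queue(k);
      for (size_t s_i = 0; s_i < far_src.size(); ++s_i) {
        int s = far_src[s_i];
        std::fill(dist.begin(), dist.end(), -1);
        dist[s] = 0;
        int head = 0, tail = 0;
        queue[tail++] = s;
        while (head < tail) {
          int u = queue[head++];
          for (size_t t = 0; t < sub[u].size(); ++t) {
            int v = sub[u][t];
            if (dist[v] < 0) {
              dist[v] = dist[u] + 1;
              queue[tail++] = v;
            }
          }
        }
        // every far pair (s, v > s) is owned by its smaller endpoint, so
        // counting d > 2 targets here counts each pair exactly once
        // (pairs at d <= 2 were already credited; unreachable pairs add 0)
        for (int v = s + 1; v < k; ++v)
          if (dist[v] > 2)
            inv_sum += 2.0 / dist[v];
      }
    }
    eff[i] = inv_sum / ((double) k * (k - 1));
    for (int a = 0; a < k; ++a) local[nb[a]] = -1;
  }
  return eff;
}

// Largest-connected-component sizes along a targeted-attack sequence.
// `order` is the full removal order (0-based node indices, length n).
// Returns an integer vector of length n + 1: entry m + 1 is the LCC size
// (number of nodes) after the first m nodes of `order` were removed;
// entry n + 1 is 0. Computed backwards by re-adding nodes with union-find.
// [[Rcpp::export]]
IntegerVector attack_lcc_cpp(const LogicalMatrix& adj, const IntegerVector& order) {
  const int n = adj.nrow();
  if (order.size() != n) stop("`order` must list all nodes exactly once");

  std::vector<int> parent(n), compsize(n, 0);
  std::vector<bool> present(n, false);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // iterative find with path halving
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int find(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } uf(parent);

  IntegerVector lcc(n + 1);
  lcc[n] = 0;
  int best = 0;
  for (int m = n - 1; m >= 0; --m) {
    int v = order[m];
    present[v] = true;
    compsize[v] = 1;
    if (compsize[v] > best) best = compsize[v];
    for (int j = 0; j < n; ++j) {
      if (adj(v, j) && present[j]) {
        int rv = uf.find(v), rj = uf.find(j);
        if (rv != rj) {
          // union by size
          if (compsize[rv] < compsize[rj]) std::swap(rv, rj);
          parent[rj] = rv;
          compsize[rv] += compsize[rj];
          if (compsize[rv] > best) best = compsize[rv];
        }
      }
    }
    lcc[m] = best;
  }
  return lcc;
}
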