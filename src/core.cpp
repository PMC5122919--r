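#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// All graph primitives operate on an adjacency list (`adj`, a list of
// 1-based integer neighbour vectors) plus an `alive` mask, so that node
// removal never mutates the source graph and schedules stay replayable.

// [[Rcpp::export]]
IntegerVector cpp_residual_degree(List adj, LogicalVector alive) {
  int n = adj.size();
  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) { deg[i] = 0; continue; }
    IntegerVector nb = adj[i];
    int d = 0;
    for (int k = 0; k < nb.size(); ++k) if (alive[nb[k] - 1]) ++d;
    deg[i] = d;
  }
  return deg;
}

// Connected components of the residual graph. Removed nodes get label 0;
// components are numbered 1, 2, ... in order of their smallest member id,
// which is what gives deterministic tie-breaking downstream.
// [[Rcpp::export]]
IntegerVector cpp_components(List adj, LogicalVector alive) {
  int n = adj.size();
  IntegerVector comp(n, 0);
  std::vector<int> stack;
  int c = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i] || comp[i] != 0) continue;
    ++c;
    comp[i] = c;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      IntegerVector nb = adj[v];
      for (int k = 0; k < nb.size(); ++k) {
        int u = nb[k] - 1;
        if (alive[u] && comp[u] == 0) { comp[u] = c; stack.push_back(u); }
      }
    }
  }
  return comp;
}

// [[Rcpp::export]]
int cpp_lcc_size(List adj, LogicalVector alive) {
  IntegerVector comp = cpp_components(adj, alive);
  int n = adj.size();
  std::vector<int> cnt;
  int best = 0;
  for (int i = 0; i < n; ++i) {
    int c = comp[i];
    if (c == 0) continue;
    if ((int)cnt.size() < c) cnt.resize(c, 0);
    if (++cnt[c - 1] > best) best = cnt[c - 1];
  }
  return best;
}

// Nodes at shortest-path distance exactly `ell` from node i (1-based) in
// the residual graph; ell = 0 returns {i}.
// [[Rcpp::export]]
IntegerVector cpp_ball_frontier(List adj, LogicalVector alive, int i, int ell) {
  int n = adj.size();
  if (ell == 0) return IntegerVector::create(i);
  std::vector<int> dist(n, -1);
  std::vector<int> cur, nxt;
  int s = i - 1;
  dist[s] = 0;
  cur.push_back(s);
  for (int d = 0; d < ell && !cur.empty(); ++d) {
    nxt.clear();
    for (size_t a = 0; a < cur.size(); ++a) {
      IntegerVector nb = adj[cur[a]];
      for (int k = 0; k < nb.size(); ++k) {
        int u = nb[k] - 1;
        if (alive[u] && dist[u] < 0) { dist[u] = d + 1; nxt.push_back(u); }
      }
    }
    cur.swap(nxt);
  }
  std::sort(cur.begin(), cur.end());
  IntegerVector out(cur.size());
  for (size_t a = 0; a < cur.size(); ++a) out[a] = cur[a] + 1;
  return out;
}

// Collective influence CI_ell(i) = (k_i - 1) * sum_{j in frontier(i, ell)} (k_j - 1)
// for every alive node, with degrees taken on the residual graph.
// ell = 0 returns k_i - 1. Removed nodes get NA.
// [[Rcpp::export]]
NumericVector cpp_ci_scores(List adj, LogicalVector alive, int ell) {
  int n = adj.size();
  IntegerVector deg = cpp_residual_degree(adj, alive);
  NumericVector out(n, NA_REAL);
  if (ell == 0) {
    for (int i = 0; i < n; ++i) if (alive[i]) out[i] = deg[i] - 1.0;
    return out;
  }
  std::vector<int> seen(n, -1);
  std::vector<int> cur, nxt;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    cur.clear();
    cur.push_back(i);
    seen[i] = i;
    for (int d = 0; d < ell && !cur.empty(); ++d) {
      nxt.clear();
      for (size_t a = 0; a < cur.size(); ++a) {
        IntegerVector nb = adj[cur[a]];
        for (int k = 0; k < nb.size(); ++k) {
          int u = nb[k] - 1;
          if (alive[u] && seen[u] != i) { seen[u] = i; nxt.push_back(u); }
        }
      }
      cur.swap(nxt);
    }
    double s = 0.0;
    for (size_t a = 0; a < cur.size(); ++a) s += deg[cur[a]] - 1.0;
    out[i] = (deg[i] - 1.0) * s;
  }
  return out;
}

// Weighted coarse adjacency: element (I, J) counts surviving edges with one
// endpoint labelled I and the other J (I != J). Diagonal stays zero.
// [[Rcpp::export]]
NumericMatrix cpp_coarse_counts(List adj, LogicalVector alive,
                                IntegerVector labels, int nc) {
  NumericMatrix A(nc, nc);
  int n = adj.size();
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    IntegerVector nb = adj[i];
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;
      if (j <= i || !alive[j]) continue;
      int I = labels[i] - 1, J = labels[j] - 1;
      if (I != J) { A(I, J) += 1.0; A(J, I) += 1.0; }
    }
  }
  return A;
}

// Per-node counts of alive neighbours outside (kout) and inside (kin) the
// node's own community.
// [[Rcpp::export]]
List cpp_cross_degrees(List adj, LogicalVector alive, IntegerVector labels) {
  int n = adj.size();
  IntegerVector kout(n), kin(n);
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    IntegerVector nb = adj[i];
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;
      if (!alive[j]) continue;
      if (labels[j] == labels[i]) ++kin[i]; else ++kout[i];
    }
  }
  return List::create(_["kout"] = kout, _["kin"] = kin);
}

// n x nc matrix of k_iJ: alive neighbours of node i inside community J.
// [[Rcpp::export]]
NumericMatrix cpp_community_degree(List adj, LogicalVector alive,
                                   IntegerVector labels, int nc) {
  int n = adj.size();
  NumericMatrix K(n, nc);
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    IntegerVector nb = adj[i];
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;
      if (alive[j]) K(i, labels[j] - 1) += 1.0;
    }
  }
  return K;
}

static int uf_find(std::vector<int>& parent, int v) {
  while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
  return v;
}

// Largest-component size after removing the first k nodes of `order`
// (a permutation of 1..n), for k = 0..n. Computed by adding nodes back in
// reverse with a union-find, so the whole curve costs ~O(M alpha(N)).
// [[Rcpp::export]]
IntegerVector cpp_removal_curve(List adj, IntegerVector order) {
  int n = adj.size();
  IntegerVector out(n + 1);
  std::vector<int> parent(n), sz(n, 0);
  std::vector<bool> present(n, false);
  out[n] = 0;
  int best = 0;
  for (int k = n; k >= 1; --k) {
    int v = order[k - 1] - 1;
    present[v] = true;
    parent[v] = v;
    sz[v] = 1;
    if (best < 1) best = 1;
    IntegerVector nb = adj[v];
    for (int a = 0; a < nb.size(); ++a) {
      int u = nb[a] - 1;
      if (!present[u]) continue;
      int rv = uf_find(parent, v), ru = uf_find(parent, u);
      if (rv == ru) continue;
      if (sz[rv] < sz[ru]) std::swap(rv, ru);
      parent[ru] = rv;
      sz[rv] += sz[ru];
      if (sz[rv] > best) best = sz[rv];
    }
    out[k - 1] = best;
  }
  return out;
}
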