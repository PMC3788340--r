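// Compiled kernels for binary-graph analysis: BFS shortest-path census,
// Brandes betweenness accumulation, neighbor-subgraph (local) efficiency,
// per-node clustering, and Maslov-Sneppen degree-preserving rewiring.
// Graphs arrive as 1-based two-column edge lists plus a node count.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static std::vector<std::vector<int>> adj_list(const IntegerMatrix &edges,
                                              int n) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  return adj;
}

// All-pairs BFS. Returns distances (R_PosInf for unreachable), optionally
// shortest-path counts, optionally Brandes betweenness (unordered pairs
// counted once, unnormalized).
// [[Rcpp::export(name = ".graph_census_cpp")]]
List graph_census_cpp(IntegerMatrix edges, int n,
                      bool want_counts, bool want_betweenness,
                      bool want_distances = true) {
  std::vector<std::vector<int>> adj = adj_list(edges, n);
  NumericMatrix dist;
  NumericMatrix counts;
  if (want_distances) dist = NumericMatrix(n, n);
  if (want_counts) counts = NumericMatrix(n, n);
  NumericVector btw(want_betweenness ? n : 0);

  std::vector<int> d(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> order_stack(n);
  std::vector<std::vector<int>> preds(n);

  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    int top = 0;
    d[s] = 0;
    sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    if (want_betweenness)
      for (int i = 0; i < n; ++i) preds[i].clear();
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      order_stack[top++] = v;
      for (int w : adj[v]) {
        if (d[w] < 0) {
          d[w] = d[v] + 1;
          q.push(w);
        }
        if (d[w] == d[v] + 1) {
          sigma[w] += sigma[v];
          if (want_betweenness) preds[w].push_back(v);
        }
      }
    }
    if (want_distances) {
      double *col = &dist[(R_xlen_t)s * n];  // fill column s (symmetric)
      for (int i = 0; i < n; ++i) col[i] = d[i] < 0 ? R_PosInf : (double)d[i];
    }
    if (want_counts) {
      double *col = &counts[(R_xlen_t)s * n];
      for (int i = 0; i < n; ++i) col[i] = d[i] < 0 ? 0.0 : sigma[i];
    }
    if (want_betweenness) {
      std::fill(delta.begin(), delta.end(), 0.0);
      for (int k = top - 1; k >= 0; --k) {
        int w = order_stack[k];
        for (int v : preds[w])
          delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
        if (w != s) btw[w] += delta[w];
      }
    }
  }
  if (want_betweenness)
    for (int i = 0; i < n; ++i) btw[i] /= 2.0;  // each pair seen from both ends

  List out = List::create(Named("distances") = want_distances
                              ? (SEXP)dist : R_NilValue,
                          Named("path_counts") = want_counts
                              ? (SEXP)counts : R_NilValue,
                          Named("betweenness") = want_betweenness
                              ? (SEXP)btw : R_NilValue);
  return out;
}

// Per-node local clustering E_i / (d_i (d_i - 1) / 2), 0 when d_i < 2.
// [[Rcpp::export(name = ".local_clustering_cpp")]]
NumericVector local_clustering_cpp(IntegerMatrix edges, int n) {
  std::vector<std::vector<int>> adj = adj_list(edges, n);
  std::vector<char> A((size_t)n * n, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    size_t a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    A[a * n + b] = A[b * n + a] = 1;
  }
  NumericVector cc(n);
  for (int i = 0; i < n; ++i) {
    int deg = adj[i].size();
    if (deg < 2) {
      cc[i] = 0.0;
      continue;
    }
    long links = 0;
    for (int u = 0; u < deg; ++u)
      for (int v = u + 1; v < deg; ++v)
        if (A[(size_t)adj[i][u] * n + adj[i][v]]) ++links;
    cc[i] = (double)links / ((double)deg * (deg - 1) / 2.0);
  }
  return cc;
}

// E_glob of the subgraph induced by each node's neighbors (node excluded);
// 0 for neighborhoods with fewer than 2 nodes.
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
NumericVector local_efficiency_cpp(IntegerMatrix edges, int n) {
  std::vector<std::vector<int>> adj = adj_list(edges, n);
  std::vector<char> A((size_t)n * n, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    size_t a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    A[a * n + b] = A[b * n + a] = 1;
  }
  NumericVector eff(n);
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &nb = adj[i];
    int m = nb.size();
    if (m < 2) {
      eff[i] = 0.0;
      continue;
    }
    // subgraph adjacency lists
    std::vector<std::vector<int>> sub(m);
    for (int u = 0; u < m; ++u)
      for (int v = u + 1; v < m; ++v)
        if (A[(size_t)nb[u] * n + nb[v]]) {
          sub[u].push_back(v);
          sub[v].push_back(u);
        }
    double inv_sum = 0.0;
    std::vector<int> d(m);
    for (int s = 0; s < m; ++s) {
      std::fill(d.begin(), d.end(), -1);
      d[s] = 0;
      std::queue<int> q;
      q.push(s);
      while (!q.empty()) {
        int v = q.front();
        q.pop();
        for (int w : sub[v])
          if (d[w] < 0) {
            d[w] = d[v] + 1;
            q.push(w);
          }
      }
      for (int t = 0; t < m; ++t)
        if (t != s && d[t] > 0) inv_sum += 1.0 / d[t];
    }
    eff[i] = inv_sum / ((double)m * (m - 1));
  }
  return eff;
}

// Maslov-Sneppen double-edge swaps: niter attempts; each picks two distinct
// edges, randomly orients them as (a,b),(c,d), and replaces them with
// (a,d),(c,b) unless the endpoints are not 4 distinct nodes or either
// replacement edge already exists. Degree sequence is invariant. Uses R's
// RNG (caller manages seeding). Returns the new edge list and the number
// of successful swaps.
// [[Rcpp::export(name = ".rewire_ms_cpp")]]
List rewire_ms_cpp(IntegerMatrix edges, int n, int niter) {
  int k = edges.nrow();
  std::vector<int> ea(k), eb(k);
  std::vector<char> A((size_t)n * n, 0);
  for (int e = 0; e < k; ++e) {
    ea[e] = edges(e, 0) - 1;
    eb[e] = edges(e, 1) - 1;
    A[(size_t)ea[e] * n + eb[e]] = A[(size_t)eb[e] * n + ea[e]] = 1;
  }
  int swaps = 0;
  for (int it = 0; it < niter; ++it) {
    int e1 = (int)(unif_rand() * k);
    int e2 = (int)(unif_rand() * k);
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(a, b);
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (A[(size_t)a * n + d] || A[(size_t)c * n + b]) continue;
    A[(size_t)a * n + b] = A[(size_t)b * n + a] = 0;
    A[(size_t)c * n + d] = A[(size_t)d * n + c] = 0;
    A[(size_t)a * n + d] = A[(size_t)d * n + a] = 1;
    A[(size_t)c * n + b] = A[(size_t)b * n + c] = 1;
    ea[e1] = a; eb[e1] = d;
    ea[e2] = c; eb[e2] = b;
    ++swaps;
  }
  IntegerMatrix out(k, 2);
  for (int e = 0; e < k; ++e) {
    out(e, 0) = std::min(ea[e], eb[e]) + 1;
    out(e, 1) = std::max(ea[e], eb[e]) + 1;
  }
  return List::create(Named("edges") = out, Named("swaps") = swaps);
}
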