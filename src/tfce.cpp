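#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// One-sided TFCE accumulation for the positive part of `u` over equal
// threshold steps h_k = k * max(u) / n_steps, k = 1..n_steps. Extent of the
// component containing a vertex is the sum of `weights` over the
// edge-connected component of {t >= h_k}.
static void tfce_one_side(const NumericVector& u,
                          const IntegerVector& e1, const IntegerVector& e2,
                          const NumericVector& weights,
                          double E, double H, int n_steps,
                          std::vector<double>& out) {
  const int V = u.size();
  const int M = e1.size();
  double umax = 0.0;
  for (int i = 0; i < V; ++i) if (u[i] > umax) umax = u[i];
  if (umax <= 0.0) return;
  const double dh = umax / n_steps;
  std::vector<int> parent(V);
  std::vector<double> compw(V);
  for (int k = 1; k <= n_steps; ++k) {
    const double h = k * dh;
    for (int i = 0; i < V; ++i) parent[i] = i;
    for (int m = 0; m < M; ++m) {
      const int a = e1[m], b = e2[m];
      if (u[a] >= h && u[b] >= h) {
        int ra = uf_find(parent, a), rb = uf_find(parent, b);
        if (ra != rb) parent[ra] = rb;
      }
    }
    std::fill(compw.begin(), compw.end(), 0.0);
    for (int i = 0; i < V; ++i) {
      if (u[i] >= h) compw[uf_find(parent, i)] += weights[i];
    }
    const double hH = std::pow(h, H);
    for (int i = 0; i < V; ++i) {
      if (u[i] >= h) {
        out[i] += std::pow(compw[uf_find(parent, i)], E) * hH * dh;
      }
    }
  }
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector t, IntegerVector e1, IntegerVector e2,
                       NumericVector weights, double E, double H,
                       int n_steps) {
  const int V = t.size();
  std::vector<double> acc_pos(V, 0.0), acc_neg(V, 0.0);
  tfce_one_side(t, e1, e2, weights, E, H, n_steps, acc_pos);
  NumericVector tneg(V);
  for (int i = 0; i < V; ++i) tneg[i] = -t[i];
  tfce_one_side(tneg, e1, e2, weights, E, H, n_steps, acc_neg);
  NumericVector out(V);
  for (int i = 0; i < V; ++i) out[i] = acc_pos[i] - acc_neg[i];
  return out;
}
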