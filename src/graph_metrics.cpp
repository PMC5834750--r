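#include <Rcpp.h>
using namespace Rcpp;

// Floyd-Warshall all-pairs shortest paths on a dense distance matrix.
// Missing edges are R_PosInf; the diagonal must be 0.
// [[Rcpp::export]]
NumericMatrix fw_apsp(NumericMatrix dist) {
  int n = dist.nrow();
  NumericMatrix d = clone(dist);
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

// Per-node Onnela weighted clustering: C_i = 2/(k_i(k_i-1)) *
// sum over unordered neighbour pairs {j,k} with an existing (j,k) edge of
// (w_ij w_jk w_ki)^(1/3). Weights must already be scaled; absent edges 0.
// [[Rcpp::export]]
NumericVector onnela_clustering_ci(NumericMatrix w) {
  int n = w.nrow();
  NumericMatrix cw(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      cw(i, j) = w(i, j) > 0 ? std::cbrt(w(i, j)) : 0.0;
  NumericVector ci(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0) nb.push_back(j);
    int k = nb.size();
    if (k < 2) { ci[i] = 0.0; continue; }
    double s = 0.0;
    for (int a = 0; a < k - 1; ++a)
      for (int b = a + 1; b < k; ++b) {
        double wjk = cw(nb[a], nb[b]);
        if (wjk > 0) s += cw(i, nb[a]) * wjk * cw(i, nb[b]);
      }
    ci[i] = 2.0 * s / (double(k) * double(k - 1));
  }
  return ci;
}

static double subgraph_eg(const NumericMatrix &w, const std::vector<int> &nodes,
                          bool reciprocal) {
  int k = nodes.size();
  if (k < 2) return 0.0;
  std::vector<double> d(k * k, R_PosInf);
  for (int a = 0; a < k; ++a) {
    d[a * k + a] = 0.0;
    for (int b = 0; b < k; ++b) {
      if (a == b) continue;
      double wab = w(nodes[a], nodes[b]);
      if (wab > 0) d[a * k + b] = reciprocal ? 1.0 / wab : wab;
    }
  }
  for (int m = 0; m < k; ++m)
    for (int a = 0; a < k; ++a) {
      double dam = d[a * k + m];
      if (!R_finite(dam)) continue;
      for (int b = 0; b < k; ++b) {
        double alt = dam + d[m * k + b];
        if (alt < d[a * k + b]) d[a * k + b] = alt;
      }
    }
  double s = 0.0;
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      if (a != b && R_finite(d[a * k + b])) s += 1.0 / d[a * k + b];
  return s / (double(k) * double(k - 1));
}

// Nodal local efficiency: E_nodal_loc(i) = global efficiency of the
// subgraph induced on the neighbours of i (node i removed), carrying the
// original scaled weights. Nodes with fewer than two neighbours get 0.
// [[Rcpp::export]]
NumericVector nodal_local_efficiency(NumericMatrix w, bool reciprocal) {
  int n = w.nrow();
  NumericVector el(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0) nb.push_back(j);
    el[i] = subgraph_eg(w, nb, reciprocal);
  }
  return el;
}
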