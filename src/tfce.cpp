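#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Path-halving union-find.
static inline int uf_find(std::vector<int>& p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

//' @title TFCE transform on a vertex graph (internal kernel)
//' @description Computes, for each vertex, the integral over height steps of
//'   (component area)^E * h^H * dh, where components are connected sets of
//'   supra-threshold vertices under the supplied edge list.  Negative and
//'   non-finite statistic values never contribute.
//' @param stat statistic per vertex
//' @param e1,e2 0-based edge endpoints
//' @param area vertex area (mm^2)
//' @param dh height step (> 0)
//' @param E,H extent and height exponents
//' @noRd
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector e1, IntegerVector e2,
                       NumericVector area, double dh, double E, double H) {
  const int V = stat.size();
  const int ne = e1.size();
  NumericVector out(V);
  double mx = 0.0;
  for (int i = 0; i < V; ++i) {
    double s = stat[i];
    if (R_finite(s) && s > mx) mx = s;
  }
  if (mx <= 0.0 || dh <= 0.0) return out;

  std::vector<int> parent(V);
  std::vector<double> carea(V);
  std::vector<char> sup(V);

  // midpoint rule over [0, max]: heights (j - 1/2) * dh
  for (double h = 0.5 * dh; h < mx; h += dh) {
    for (int i = 0; i < V; ++i) {
      double s = stat[i];
      sup[i] = (R_finite(s) && s >= h) ? 1 : 0;
      parent[i] = i;
      carea[i] = sup[i] ? area[i] : 0.0;
    }
    for (int k = 0; k < ne; ++k) {
      int a = e1[k], b = e2[k];
      if (sup[a] && sup[b]) {
        int ra = uf_find(parent, a), rb = uf_find(parent, b);
        if (ra != rb) { parent[rb] = ra; carea[ra] += carea[rb]; }
      }
    }
    double hH = std::pow(h, H);
    for (int i = 0; i < V; ++i) {
      if (sup[i]) {
        int r = uf_find(parent, i);
        out[i] += std::pow(carea[r], E) * hH * dh;
      }
    }
  }
  return out;
}
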