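#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

//' @title L2-regularized L1-loss linear SVM by dual coordinate descent
//' @description Solves min_w 0.5*||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
//'   with deterministic cyclic coordinate order (Hsieh et al. 2008 without
//'   random shuffling, so identical inputs give identical weights).  A bias
//'   term, if wanted, must be supplied as a constant feature column.
//' @param X n x d feature matrix
//' @param y labels in {-1, +1}
//' @param C cost parameter
//' @param max_iter maximum number of passes over the data
//' @param tol stop when the largest projected gradient in a pass is below tol
//' @noRd
// [[Rcpp::export(name = ".svm_linear_cpp")]]
NumericVector svm_linear_cpp(NumericMatrix X, NumericVector y, double C,
                             int max_iter, double tol) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int j = 0; j < d; ++j) { double v = X(i, j); s += v * v; }
    Qii[i] = std::max(s, 1e-12);
  }
  for (int it = 0; it < max_iter; ++it) {
    double worst = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = 0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0)      PG = std::min(G, 0.0);
      else if (alpha[i] >= C)   PG = std::max(G, 0.0);
      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / Qii[i], 0.0), C);
        alpha[i] = a_new;
        double dc = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += dc * X(i, j);
      }
      if (std::fabs(PG) > worst) worst = std::fabs(PG);
    }
    if (worst < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
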