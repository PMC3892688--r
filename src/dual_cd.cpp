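#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i)
// with the intercept carried as an augmented constant feature (value 1),
// following the standard large-scale linear-SVM formulation. The dual is
// box-constrained QP; coordinates are swept in random order (R's RNG, so
// set.seed() makes runs reproducible) and convergence is declared when the
// largest projected gradient over a sweep falls below eps.
// [[Rcpp::export]]
List svm_dual_cd(NumericMatrix X, NumericVector y, NumericVector C,
                 int max_epochs = 1000, double eps = 1e-6) {
  const int n = X.nrow(), d = X.ncol();
  // contiguous per-sample layout (samples as columns) so the inner dot
  // products stream through memory
  std::vector<double> Xt((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      Xt[(size_t)i * d + j] = X(i, j);
  std::vector<double> w(d + 1, 0.0); // last entry: bias weight
  std::vector<double> alpha(n, 0.0);
  std::vector<double> Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // bias feature
    const double* xi = &Xt[(size_t)i * d];
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    Qii[i] = s;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  bool converged = false;
  int epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      const double* xi = &Xt[(size_t)i * d];
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      const double G = y[i] * wx - 1.0;
      double pg = G;
      if (alpha[i] <= 0.0 && G >= 0.0) pg = 0.0;
      else if (alpha[i] >= C[i] && G <= 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C[i]) a_new = C[i];
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          w[d] += delta;
        }
      }
    }
    if (max_pg < eps) { converged = true; break; }
  }
  NumericVector wv(d);
  for (int j = 0; j < d; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[d],
                      _["epochs"] = std::min(epoch, max_epochs),
                      _["converged"] = converged);
}
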