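#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Dual coordinate descent for the linear L1-loss C-SVM (the liblinear
// algorithm), with the bias handled as an augmented constant feature.
//
// dual: min_a 1/2 a' Q a - e' a, 0 <= a_i <= C,
//       Q_ij = y_i y_j (x_i . x_j + B^2)
//
// Returns the primal weight vector of length d + 1; the last entry is
// the weight of the bias feature (decision value f(x) = w.x + B * w_b).
//
// [[Rcpp::export]]
NumericVector svm_dcd_train(NumericMatrix X, NumericVector y, double cost,
                            double bias, int max_passes, double tol,
                            int seed) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qdiag(n);
  for (int i = 0; i < n; ++i) {
    double s = bias * bias;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qdiag[i] = s;
  }
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int pass = 0; pass < max_passes; ++pass) {
    std::shuffle(order.begin(), order.end(), rng);
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      double f = bias * w[d];
      for (int j = 0; j < d; ++j) f += X(i, j) * w[j];
      const double G = y[i] * f - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= cost && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        double a_new = alpha[i] - G / qdiag[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > cost) a_new = cost;
        const double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          w[d] += delta * bias;
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  NumericVector out(d + 1);
  for (int j = 0; j <= d; ++j) out[j] = w[j];
  return out;
}
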