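#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss linear SVM with the bias as an
// augmented constant feature (liblinear formulation):
//   min_w 0.5||w||^2 + C sum_i max(0, 1 - y_i w.x~_i),  x~ = (x, 1).
// Returns the weight vector (without the bias component), the bias, the
// dual variables, and the number of passes used.

// [[Rcpp::export]]
List svm_dcd_cpp(const NumericMatrix& X, const NumericVector& y,
                 double cost, double tol, int max_pass) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), q(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;                       // bias feature contributes 1
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    q[i] = s;
  }
  int pass = 0;
  for (; pass < max_pass; ++pass) {
    double maxpg = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      const double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= cost) pg = std::max(g, 0.0);
      if (std::abs(pg) > maxpg) maxpg = std::abs(pg);
      if (std::abs(pg) > 1e-13) {
        const double a_new =
          std::min(std::max(alpha[i] - g / q[i], 0.0), cost);
        const double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (maxpg < tol) break;
  }
  NumericVector wv(d);
  for (int j = 0; j < d; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[d],
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["passes"] = pass + 1);
}
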