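#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM,
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i),
// with the bias handled through an augmented constant feature (value 1),
// following the LIBLINEAR algorithm (Hsieh et al., 2008). Coordinates
// are visited in an epoch-wise shuffled order driven by an internal
// fixed-seed LCG, so results depend only on the data (shuffling matters:
// cyclic order converges poorly on strongly correlated features such as
// rank-1 channel data). Default tolerance matches LIBLINEAR's 0.1 on
// the maximal projected gradient.
//
// X: n x p feature matrix, y: +1/-1 labels. Returns w of length p + 1,
// the last entry being the bias weight; the decision value for a row x
// is w[0:p-1].x + w[p].
// [[Rcpp::export]]
NumericVector linsvm_fit(const NumericMatrix& X, const NumericVector& y,
                         double cost = 1.0, double tol = 0.1,
                         int max_epochs = 200) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector w(p + 1);
  std::vector<double> alpha(n, 0.0), qii(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long rng = 88172645463325252ULL;
  auto next_u = [&rng]() {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    return rng;
  };
  for (int i = 0; i < n; ++i) {
    double q = 1.0;  // augmented bias feature
    for (int j = 0; j < p; ++j) q += X(i, j) * X(i, j);
    qii[i] = q;
  }
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i)
      std::swap(order[i], order[next_u() % (i + 1)]);
    double pg_max = -1e30, pg_min = 1e30;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      double wx = w[p];
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      const double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= cost) pg = std::max(g, 0.0);
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha[i];
        double a = a_old - g / qii[i];
        a = std::min(std::max(a, 0.0), cost);
        alpha[i] = a;
        const double d = (a - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          w[p] += d;
        }
      }
    }
    if (pg_max - pg_min < tol) break;
  }
  return w;
}
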