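#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen training loop. Patterns are presented in the precomputed
// seeded orders (one column per epoch); at global presentation t the
// learning rate is eta0*exp(-t/tau2) and the neighborhood radius
// sigma0*exp(-t/tau1). Supervised training finds the winner on the weighted
// combination x_weight*dX^2 + (1-x_weight)*dY^2 and updates both layers.
// The per-epoch history records the mean squared quantization error on the
// X layer (X-only winner), and training stops early when its relative
// improvement over an epoch falls below stop_tol.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix x, NumericMatrix y,
                   NumericMatrix wx0, NumericMatrix wy0,
                   NumericMatrix grid_d2, IntegerMatrix orders,
                   double eta0, double tau2, double sigma0, double tau1,
                   double x_weight, int n_epochs, double stop_tol,
                   bool supervised) {
  const int n = x.nrow(), p = x.ncol(), m = wx0.nrow();
  const int q = supervised ? 2 : 0;
  NumericMatrix wx(clone(wx0));
  NumericMatrix wy(clone(wy0));
  std::vector<double> history;
  history.reserve(n_epochs);

  double t = 0.0;
  int epochs_run = 0;
  double prev_qe = R_PosInf;

  for (int e = 0; e < n_epochs; ++e) {
    for (int ii = 0; ii < n; ++ii) {
      const int i = orders(ii, e) - 1;
      // find winner
      int bmu = 0;
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double dx2 = 0.0;
        for (int c = 0; c < p; ++c) {
          const double d = x(i, c) - wx(k, c);
          dx2 += d * d;
        }
        double dd = dx2;
        if (supervised) {
          double dy2 = 0.0;
          for (int c = 0; c < q; ++c) {
            const double d = y(i, c) - wy(k, c);
            dy2 += d * d;
          }
          dd = x_weight * dx2 + (1.0 - x_weight) * dy2;
        }
        if (dd < best) { best = dd; bmu = k; }  // strict <: lowest index wins ties
      }
      // update all nodes
      const double eta = eta0 * std::exp(-t / tau2);
      const double sigma = sigma0 * std::exp(-t / tau1);
      const double s2 = 2.0 * sigma * sigma;
      for (int k = 0; k < m; ++k) {
        double h;
        if (k == bmu) h = eta;
        else if (s2 <= 0.0) continue;  // collapsed neighborhood: BMU only
        else {
          h = eta * std::exp(-grid_d2(k, bmu) / s2);
          if (h <= 0.0) continue;
        }
        for (int c = 0; c < p; ++c)
          wx(k, c) += h * (x(i, c) - wx(k, c));
        if (supervised)
          for (int c = 0; c < q; ++c)
            wy(k, c) += h * (y(i, c) - wy(k, c));
      }
      t += 1.0;
    }
    // epoch quantization error, X layer only
    double qe = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double dx2 = 0.0;
        for (int c = 0; c < p; ++c) {
          const double d = x(i, c) - wx(k, c);
          dx2 += d * d;
        }
        if (dx2 < best) best = dx2;
      }
      qe += best;
    }
    qe /= n;
    history.push_back(qe);
    epochs_run = e + 1;
    if (R_finite(prev_qe) && prev_qe > 0.0) {
      const double rel = (prev_qe - qe) / prev_qe;
      if (rel < stop_tol) break;
    }
    prev_qe = qe;
  }

  return List::create(
    _["wx"] = wx, _["wy"] = wy,
    _["history"] = NumericVector(history.begin(), history.end()),
    _["epochs_run"] = epochs_run,
    _["presentations"] = (double) epochs_run * n);
}
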