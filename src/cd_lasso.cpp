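#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted-penalty L1 logistic regression along a decreasing lambda path.
//
// Minimizes, for each lambda in `lambda`:
//     sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ] + lambda * sum_j w_j |beta_j|
// with eta = b0 + X beta and an unpenalized intercept, by iteratively
// reweighted least squares (quadratic approximation of the logistic
// likelihood) with cyclic coordinate descent and soft-thresholding on the
// inner problem. Warm starts carry coefficients down the path, so exact
// zeros from the soft-threshold are preserved. X is expected pre-scaled
// (the R wrapper standardizes); columns with negligible weighted norm keep
// a zero coefficient.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                   NumericVector penalty_weights, double tol = 1e-7,
                   int max_outer = 100, int max_inner = 1000) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  NumericMatrix beta_out(p, nl);
  NumericVector b0_out(nl);
  IntegerVector outer_iters(nl);
  LogicalVector conv(nl);

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double yb = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double b0 = std::log(yb / (1.0 - yb));

  std::vector<double> eta(n, b0), w(n), r(n), xwx(p);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    bool converged = false;
    int outer = 0;
    for (; outer < max_outer && !converged; ++outer) {
      // quadratic approximation at current (b0, beta)
      double max_irls_change = 0.0;
      for (int i = 0; i < n; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-eta[i]));
        if (pi < 1e-5) pi = 1e-5;
        if (pi > 1.0 - 1e-5) pi = 1.0 - 1e-5;
        w[i] = pi * (1.0 - pi);
        // working residual z_i - eta_i with z = eta + (y - p)/w
        r[i] = (y[i] - pi) / w[i];
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) { const double xij = X(i, j); s += w[i] * xij * xij; }
        xwx[j] = s;
      }
      // inner coordinate descent on the penalized weighted least squares:
      // full sweeps over all coordinates alternate with cheap sweeps over
      // the active (nonzero) set, glmnet-style
      auto update_coord = [&](int j) -> double {
        if (xwx[j] < 1e-12) return 0.0;
        const double bj = beta[j];
        double xwr = 0.0;
        for (int i = 0; i < n; ++i) xwr += w[i] * X(i, j) * r[i];
        const double bnew = soft(xwr + xwx[j] * bj, lam * penalty_weights[j]) / xwx[j];
        const double d = bnew - bj;
        if (d != 0.0) {
          beta[j] = bnew;
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        }
        return std::fabs(d);
      };
      auto update_intercept = [&]() -> double {
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
        const double d0 = swr / sw;
        if (d0 != 0.0) {
          b0 += d0;
          for (int i = 0; i < n; ++i) r[i] -= d0;
        }
        return std::fabs(d0);
      };
      int inner_used = 0;
      for (int cycle = 0; cycle < max_inner; ++cycle) {
        // one full sweep
        double maxdiff = update_intercept();
        for (int j = 0; j < p; ++j) {
          const double d = update_coord(j);
          if (d > maxdiff) maxdiff = d;
        }
        if (maxdiff < tol) break;
        // iterate on the active set until it converges
        std::vector<int> active;
        active.reserve(p);
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
        while (inner_used < max_inner) {
          ++inner_used;
          double amax = update_intercept();
          for (size_t a = 0; a < active.size(); ++a) {
            const double d = update_coord(active[a]);
            if (d > amax) amax = d;
          }
          if (amax < tol) break;
        }
      }
      // refresh eta from the solved quadratic problem and test outer change
      double max_eta_change = 0.0;
      for (int i = 0; i < n; ++i) {
        double eta_new = b0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0) eta_new += X(i, j) * beta[j];
        const double d = std::fabs(eta_new - eta[i]);
        if (d > max_eta_change) max_eta_change = d;
        eta[i] = eta_new;
      }
      max_irls_change = max_eta_change;
      if (max_irls_change < std::sqrt(tol)) converged = true;
    }
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    b0_out[l] = b0;
    outer_iters[l] = outer;
    conv[l] = converged;
  }
  return List::create(_["beta"] = beta_out, _["intercept"] = b0_out,
                      _["outer_iters"] = outer_iters,
                      _["converged"] = conv);
}
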