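#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent solver for the squared-error LASSO path
//   argmin_{a0, b} (1/2n) || y - a0 - X b ||^2 + lambda * ||b||_1
// X columns are expected pre-standardized (zero mean); the intercept is
// unpenalized.  Lambdas must be decreasing; solutions are warm-started
// along the path.  Active-set strategy: converge coordinate descent on
// the ever-active columns, then a Karush-Kuhn-Tucker pass over all
// columns admits violators; repeat until no violations.  Convergence:
// largest weighted squared coordinate update below thresh * var(y).
// [[Rcpp::export]]
List lasso_cd_path(const NumericMatrix& X, const NumericVector& y,
                   const NumericVector& lambda, double thresh,
                   int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix beta(p, L);
  NumericVector a0(L);

  std::vector<double> colsq(p);        // (1/n) sum x_ij^2
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    colsq[j] = s / n;
  }

  double ybar = 0.0, yvar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ybar) * (y[i] - ybar);
  yvar /= n;
  if (yvar <= 0.0) yvar = 1.0;
  const double tol = thresh * yvar;

  std::vector<double> b(p, 0.0);
  std::vector<double> r(n);            // residual y - a0 - X b
  double icpt = ybar;
  for (int i = 0; i < n; ++i) r[i] = y[i] - icpt;

  std::vector<int> active;
  std::vector<char> in_active(p, 0);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int round = 0; round < 100; ++round) {
      // converge on the current active set
      for (int it = 0; it < max_iter; ++it) {
        double maxdel = 0.0;
        for (size_t jj = 0; jj < active.size(); ++jj) {
          const int j = active[jj];
          if (colsq[j] <= 0.0) continue;
          double rho = 0.0;
          for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
          rho = rho / n + colsq[j] * b[j];
          double bn = 0.0;
          if (rho > lam) bn = (rho - lam) / colsq[j];
          else if (rho < -lam) bn = (rho + lam) / colsq[j];
          const double del = bn - b[j];
          if (del != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= X(i, j) * del;
            b[j] = bn;
            const double d2 = colsq[j] * del * del;
            if (d2 > maxdel) maxdel = d2;
          }
        }
        // re-center the intercept
        double rbar = 0.0;
        for (int i = 0; i < n; ++i) rbar += r[i];
        rbar /= n;
        if (rbar != 0.0) {
          icpt += rbar;
          for (int i = 0; i < n; ++i) r[i] -= rbar;
          const double d2 = rbar * rbar;
          if (d2 > maxdel) maxdel = d2;
        }
        if (maxdel < tol) break;
      }
      // KKT pass: admit columns whose gradient violates the bound
      bool violated = false;
      for (int j = 0; j < p; ++j) {
        if (in_active[j] || colsq[j] <= 0.0) continue;
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
        rho /= n;
        if (rho > lam + 1e-12 || rho < -(lam + 1e-12)) {
          in_active[j] = 1;
          active.push_back(j);
          violated = true;
        }
      }
      if (!violated) break;
    }
    for (size_t jj = 0; jj < active.size(); ++jj)
      beta(active[jj], l) = b[active[jj]];
    a0[l] = icpt;
  }
  return List::create(_["beta"] = beta, _["a0"] = a0);
}
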