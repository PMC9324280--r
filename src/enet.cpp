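// Elastic-net penalised logistic regression by IRLS + cyclic coordinate
// descent, the AdaBoost-boosted chain of such learners, and the repeated
// (RENT) subsampling loop.  All loops live here because the ensemble
// selector needs ~10^5-10^6 weak fits per experiment.
//
// Objective (observation weights v normalised to sum 1):
//   f(b0, beta) = sum_i v_i * [-y_i eta_i + log(1 + exp(eta_i))]
//                 + lambda * (alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2)
// with eta = b0 + X beta.  This matches the glmnet parameterisation for
// family = "binomial" with standardize = FALSE.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Core solver.  X is column-major n x p.  v must sum to 1.
// Returns the number of IRLS iterations used; sets converged flag.
static int enet_solve(const double* X, const double* y, const double* v,
                      int n, int p, double lambda, double alpha,
                      int maxit, double tol,
                      std::vector<double>& beta, double& b0,
                      bool& converged) {
  const double pmin = 1e-5;
  std::vector<double> eta(n), w(n), z(n), r(n), xwx(p);
  converged = false;
  int outer_max = maxit < 100 ? maxit : 100;
  if (outer_max < 1) outer_max = 1;
  int outer;
  for (outer = 0; outer < outer_max; ++outer) {
    // Working response from current estimates.
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X[(size_t)j * n + i] * beta[j];
      eta[i] = e;
      double pr = 1.0 / (1.0 + std::exp(-e));
      if (pr < pmin) pr = pmin;
      if (pr > 1.0 - pmin) pr = 1.0 - pmin;
      double d = pr * (1.0 - pr);
      w[i] = v[i] * d;
      z[i] = e + (y[i] - pr) / d;
      r[i] = z[i] - e;  // working residual
    }
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) wsum += w[i];
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      const double* xj = X + (size_t)j * n;
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
      xwx[j] = s;
    }
    // Inner coordinate descent on the penalised WLS problem with an
    // active-set strategy: full sweeps locate the active set, then cheap
    // sweeps iterate over the non-zero coefficients only.  Sweep caps
    // keep quasi-separable reweighted subproblems cheap; the outer IRLS
    // loop restores precision by re-linearising.
    double outer_delta = 0.0;
    auto update_coord = [&](int j) -> double {
      if (xwx[j] <= 0.0) { beta[j] = 0.0; return 0.0; }
      const double* xj = X + (size_t)j * n;
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
      num += beta[j] * xwx[j];
      double bj = soft_threshold(num, lambda * alpha) /
                  (xwx[j] + lambda * (1.0 - alpha));
      double d = bj - beta[j];
      if (d != 0.0) {
        beta[j] = bj;
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      }
      return std::fabs(d);
    };
    auto update_intercept = [&]() -> double {
      double num0 = 0.0;
      for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
      double d0 = num0 / wsum;
      if (d0 != 0.0) {
        b0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
      }
      return std::fabs(d0);
    };
    for (int cycle = 0; cycle < 10; ++cycle) {
      // One full sweep over all coordinates.
      double maxdelta = update_intercept();
      for (int j = 0; j < p; ++j) {
        double ad = update_coord(j);
        if (ad > maxdelta) maxdelta = ad;
      }
      if (maxdelta > outer_delta) outer_delta = maxdelta;
      if (maxdelta < tol) break;
      // Active-set sweeps over current non-zeros.
      std::vector<int> active;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      for (int sweep = 0; sweep < 50; ++sweep) {
        double md = update_intercept();
        for (size_t a = 0; a < active.size(); ++a) {
          double ad = update_coord(active[a]);
          if (ad > md) md = ad;
        }
        if (md > outer_delta) outer_delta = md;
        if (md < tol) break;
      }
    }
    if (outer_delta < tol * 10.0) { converged = true; ++outer; break; }
  }
  return outer;
}

// [[Rcpp::export]]
List enet_fit_cpp(NumericMatrix X, NumericVector y, NumericVector weights,
                  double lambda, double alpha, int maxit, double tol) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> v(n);
  double ws = 0.0;
  for (int i = 0; i < n; ++i) ws += weights[i];
  for (int i = 0; i < n; ++i) v[i] = weights[i] / ws;
  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;
  bool conv = false;
  int it = enet_solve(REAL(X), REAL(y), v.data(), n, p, lambda, alpha,
                      maxit, tol, beta, b0, conv);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = b0,
                      _["converged"] = conv,
                      _["iterations"] = it);
}

// Discrete two-class AdaBoost over elastic-net logistic weak learners.
// Predictions are thresholded at probability 0.5; boosting coefficient
// beta_m = 0.5 * log((1 - eps_m) / eps_m); stop when eps_m >= 0.5,
// eps_m == 0, or the chain reaches N learners.  If the *first* learner
// already has eps >= 0.5 the chain falls back to that single learner with
// unit weight and is flagged.
// Returns per-learner coefficients, boosting weights, and the
// normalised-weight aggregate coefficient vector.
static void boosted_solve(const double* X, const double* y, int n, int p,
                          double lambda, double alpha, int N,
                          int maxit, double tol,
                          std::vector<std::vector<double> >& coefs,
                          std::vector<double>& intercepts,
                          std::vector<double>& bweights,
                          std::vector<double>& errors,
                          bool& fallback) {
  std::vector<double> v(n, 1.0 / n);
  fallback = false;
  const double eps_floor = 1e-10;
  for (int m = 0; m < N; ++m) {
    std::vector<double> beta(p, 0.0);
    double b0 = 0.0;
    bool conv = false;
    enet_solve(X, y, v.data(), n, p, lambda, alpha, maxit, tol, beta, b0, conv);
    // Weighted 0/1 error of the thresholded prediction.
    std::vector<int> wrong(n);
    double eps = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X[(size_t)j * n + i] * beta[j];
      int yhat = e >= 0.0 ? 1 : 0;
      wrong[i] = (yhat != (int)y[i]);
      if (wrong[i]) eps += v[i];
    }
    if (eps >= 0.5) {
      if (m == 0) {  // degenerate first learner: keep it, flag, stop
        coefs.push_back(beta);
        intercepts.push_back(b0);
        bweights.push_back(1.0);
        errors.push_back(eps);
        fallback = true;
      }
      break;
    }
    double eps_c = eps < eps_floor ? eps_floor : eps;
    double bm = 0.5 * std::log((1.0 - eps_c) / eps_c);
    coefs.push_back(beta);
    intercepts.push_back(b0);
    bweights.push_back(bm);
    errors.push_back(eps);
    if (eps <= 0.0) break;  // perfect learner: nothing left to reweight
    // Reweight: multiply by exp(+bm) when wrong, exp(-bm) when right.
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      v[i] *= std::exp(wrong[i] ? bm : -bm);
      s += v[i];
    }
    for (int i = 0; i < n; ++i) v[i] /= s;
  }
}

// [[Rcpp::export]]
List boosted_enet_cpp(NumericMatrix X, NumericVector y,
                      double lambda, double alpha, int N,
                      int maxit, double tol) {
  int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<double> > coefs;
  std::vector<double> intercepts, bweights, errors;
  bool fallback = false;
  boosted_solve(REAL(X), REAL(y), n, p, lambda, alpha, N, maxit, tol,
                coefs, intercepts, bweights, errors, fallback);
  int M = (int)coefs.size();
  NumericMatrix L(M, p);
  NumericVector ic(M), bw(M), er(M), agg(p);
  double agg0 = 0.0, bwsum = 0.0;
  for (int m = 0; m < M; ++m) bwsum += bweights[m];
  for (int m = 0; m < M; ++m) {
    for (int j = 0; j < p; ++j) L(m, j) = coefs[m][j];
    ic[m] = intercepts[m];
    bw[m] = bweights[m];
    er[m] = errors[m];
    double wnorm = bwsum > 0 ? bweights[m] / bwsum : 1.0 / M;
    for (int j = 0; j < p; ++j) agg[j] += wnorm * coefs[m][j];
    agg0 += wnorm * intercepts[m];
  }
  return List::create(_["learners"] = L, _["intercepts"] = ic,
                      _["boost_weights"] = bw, _["errors"] = er,
                      _["aggregated_coeffs"] = agg,
                      _["aggregated_intercept"] = agg0,
                      _["fallback"] = fallback);
}

// K repeated fits on random subsamples (without replacement, fraction of n),
// each fit on the subsample's standardised predictors; returns the K x p
// matrix of (aggregated, if boosted) coefficient vectors.  Uses the R RNG so
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
NumericMatrix rent_coef_runs_cpp(NumericMatrix X, NumericVector y,
                                 double lambda, double alpha,
                                 int K, double fraction,
                                 bool boosted, int N,
                                 int maxit, double tol) {
  int n = X.nrow(), p = X.ncol();
  int m = (int)std::lround(fraction * n);
  if (m < 2) m = 2;
  if (m > n) m = n;
  NumericMatrix out(K, p);
  std::vector<double> Xs((size_t)m * p), ys(m);
  for (int k = 0; k < K; ++k) {
    IntegerVector idx;
    // Re-draw (bounded) if the subsample is single-class.
    for (int attempt = 0; attempt < 25; ++attempt) {
      idx = Rcpp::sample(n, m, false);  // 1-based
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += y[idx[i] - 1];
      if (s > 0.0 && s < m) break;
    }
    for (int i = 0; i < m; ++i) ys[i] = y[idx[i] - 1];
    // Standardise each column within the subsample (sample sd, n-1).
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double mu = 0.0;
      for (int i = 0; i < m; ++i) mu += xj[idx[i] - 1];
      mu /= m;
      double ss = 0.0;
      for (int i = 0; i < m; ++i) {
        double d = xj[idx[i] - 1] - mu;
        ss += d * d;
      }
      double sd = m > 1 ? std::sqrt(ss / (m - 1)) : 0.0;
      double* col = &Xs[(size_t)j * m];
      if (sd < 1e-12) {
        for (int i = 0; i < m; ++i) col[i] = 0.0;
      } else {
        for (int i = 0; i < m; ++i) col[i] = (xj[idx[i] - 1] - mu) / sd;
      }
    }
    if (boosted) {
      std::vector<std::vector<double> > coefs;
      std::vector<double> intercepts, bweights, errors;
      bool fb = false;
      boosted_solve(Xs.data(), ys.data(), m, p, lambda, alpha, N,
                    maxit, tol, coefs, intercepts, bweights, errors, fb);
      double bwsum = 0.0;
      for (size_t q = 0; q < bweights.size(); ++q) bwsum += bweights[q];
      for (size_t q = 0; q < coefs.size(); ++q) {
        double wq = bwsum > 0 ? bweights[q] / bwsum : 1.0 / coefs.size();
        for (int j = 0; j < p; ++j) out(k, j) += wq * coefs[q][j];
      }
    } else {
      std::vector<double> beta(p, 0.0);
      double b0 = 0.0;
      bool conv = false;
      std::vector<double> v(m, 1.0 / m);
      enet_solve(Xs.data(), ys.data(), v.data(), m, p, lambda, alpha,
                 maxit, tol, beta, b0, conv);
      for (int j = 0; j < p; ++j) out(k, j) = beta[j];
    }
  }
  return out;
}
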