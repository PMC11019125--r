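// Cyclic coordinate descent for the elastic-net objective
//   (1/2N) * sum_i (y_i - x_i' b)^2 + lambda * ((1-alpha)/2 ||b||_2^2
//                                               + alpha ||b||_1)
// on centered X and y (the intercept is handled in R). Residual-update
// scheme. The path solver adds sequential strong-rule screening
// (|x_j'r|/N >= alpha*(2*lambda_l - lambda_{l-1}) keeps a coordinate in
// play) with a full KKT pass per lambda to catch rule violations; full
// gradients go through BLAS dgemv.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double objective(const NumericVector& r, const NumericVector& beta,
                        double lambda, double alpha, int N) {
  double rss = 0.0, l1 = 0.0, l2 = 0.0;
  for (int i = 0; i < r.size(); ++i) rss += r[i] * r[i];
  for (int j = 0; j < beta.size(); ++j) {
    l1 += std::fabs(beta[j]);
    l2 += beta[j] * beta[j];
  }
  return rss / (2.0 * N) + lambda * ((1.0 - alpha) * l2 / 2.0 + alpha * l1);
}

// one pass over the coordinates listed in idx; returns max |delta beta|
static double sweep_set(const NumericMatrix& X, NumericVector& r,
                        NumericVector& beta, const NumericVector& v,
                        const std::vector<int>& idx, double lambda,
                        double alpha, int N) {
  double maxChange = 0.0;
  const double la = lambda * alpha;
  const double lr = lambda * (1.0 - alpha);
  for (size_t t = 0; t < idx.size(); ++t) {
    int j = idx[t];
    double denom = v[j] + lr;
    if (denom <= 0.0) continue;      // zero-variance column at lambda 0
    double dot = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < N; ++i) dot += xj[i] * r[i];
    double rho = dot / N + v[j] * beta[j];
    double bnew = soft(rho, la) / denom;
    double delta = bnew - beta[j];
    if (delta != 0.0) {
      for (int i = 0; i < N; ++i) r[i] -= delta * xj[i];
      beta[j] = bnew;
      double ad = std::fabs(delta);
      if (ad > maxChange) maxChange = ad;
    }
  }
  return maxChange;
}

// iterate coordinate descent on a candidate set until stable;
// returns sweeps used (full candidate sweeps + active-set refinements)
static int cd_on_set(const NumericMatrix& X, NumericVector& r,
                     NumericVector& beta, const NumericVector& v,
                     const std::vector<int>& cand, double lambda,
                     double alpha, int N, double tolAbs, int maxit,
                     int sweepsSoFar, bool* converged) {
  int sweeps = sweepsSoFar;
  *converged = false;
  while (sweeps < maxit) {
    double ch = sweep_set(X, r, beta, v, cand, lambda, alpha, N);
    ++sweeps;
    if (ch < tolAbs) { *converged = true; break; }
    std::vector<int> act;
    for (size_t t = 0; t < cand.size(); ++t)
      if (beta[cand[t]] != 0.0) act.push_back(cand[t]);
    while (sweeps < maxit) {
      double cha = sweep_set(X, r, beta, v, act, lambda, alpha, N);
      ++sweeps;
      if (cha < tolAbs) break;
    }
  }
  return sweeps;
}

// g = X' r / N via BLAS
static void full_gradient(const NumericMatrix& X, const NumericVector& r,
                          NumericVector& g) {
  const int N = X.nrow(), p = X.ncol();
  const double one = 1.0, zero = 0.0;
  const int inc = 1;
  F77_CALL(dgemv)("T", &N, &p, &one, X.begin(), &N, r.begin(), &inc,
                  &zero, g.begin(), &inc FCONE);
  for (int j = 0; j < p; ++j) g[j] /= N;
}

// [[Rcpp::export(name = ".enetFitCpp")]]
List enetFitCpp(NumericMatrix X, NumericVector y, double alpha,
                double lambda, NumericVector betaInit, double tolAbs,
                int maxit, bool trace) {
  const int N = X.nrow(), p = X.ncol();
  NumericVector beta = clone(betaInit);
  NumericVector v(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < N; ++i) s += xj[i] * xj[i];
    v[j] = s / N;
  }
  NumericVector r(N);
  for (int i = 0; i < N; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0) {
      const double* xj = &X(0, j);
      for (int i = 0; i < N; ++i) r[i] -= xj[i] * beta[j];
    }
  std::vector<int> allIdx(p);
  for (int j = 0; j < p; ++j) allIdx[j] = j;

  std::vector<double> objTrace;
  int sweeps = 0;
  bool converged = false;
  while (sweeps < maxit) {
    double ch = sweep_set(X, r, beta, v, allIdx, lambda, alpha, N);
    ++sweeps;
    if (trace) objTrace.push_back(objective(r, beta, lambda, alpha, N));
    if (ch < tolAbs) { converged = true; break; }
    std::vector<int> act;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
    while (sweeps < maxit) {
      double cha = sweep_set(X, r, beta, v, act, lambda, alpha, N);
      ++sweeps;
      if (trace) objTrace.push_back(objective(r, beta, lambda, alpha, N));
      if (cha < tolAbs) break;
    }
  }
  return List::create(_["beta"] = beta, _["nIter"] = sweeps,
                      _["converged"] = converged,
                      _["objective"] = objective(r, beta, lambda, alpha, N),
                      _["objTrace"] = wrap(objTrace));
}

// [[Rcpp::export(name = ".enetPathCpp")]]
List enetPathCpp(NumericMatrix X, NumericVector y, double alpha,
                 NumericVector lambdas, double tolAbs, int maxit) {
  const int N = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix betas(p, L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  NumericVector beta(p), v(p), g(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < N; ++i) s += xj[i] * xj[i];
    v[j] = s / N;
  }
  NumericVector r = clone(y);                 // beta starts at zero
  double lambdaPrev = R_PosInf;
  for (int l = 0; l < L; ++l) {
    const double lambda = lambdas[l];
    const double la = lambda * alpha;
    full_gradient(X, r, g);
    // sequential strong rule; always keep the current support
    double strong = (lambdaPrev == R_PosInf)
      ? la : alpha * (2.0 * lambda - lambdaPrev);
    std::vector<int> cand;
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0 || std::fabs(g[j]) >= strong) cand.push_back(j);
    int sweeps = 0;
    bool ok = false;
    for (int round = 0; round < 100; ++round) {
      sweeps = cd_on_set(X, r, beta, v, cand, lambda, alpha, N, tolAbs,
                         maxit, sweeps, &ok);
      if (!ok) break;
      // KKT pass over the excluded coordinates
      full_gradient(X, r, g);
      std::vector<int> viol;
      std::vector<bool> inCand(p, false);
      for (size_t t = 0; t < cand.size(); ++t) inCand[cand[t]] = true;
      for (int j = 0; j < p; ++j)
        if (!inCand[j] && std::fabs(g[j]) > la + tolAbs) viol.push_back(j);
      if (viol.empty()) break;
      for (size_t t = 0; t < viol.size(); ++t) cand.push_back(viol[t]);
      ok = false;
    }
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    iters[l] = sweeps;
    conv[l] = ok;
    lambdaPrev = lambda;
  }
  return List::create(_["beta"] = betas, _["nIter"] = iters,
                      _["converged"] = conv);
}
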