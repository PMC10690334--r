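// Hot paths of the MCFF trial likelihood and the componentwise
// random-walk Metropolis update. All randomness goes through R's RNG so
// results are reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Decode a log10-scale parameter vector into component magnitudes.
// delta[0] = d[0] = 0: no forgetting step or relearning asymptote in
// session 1. K must be 2, 6 or 14 (validated on the R side).
static void decode(const double* th, int K, int S, double& gamma, double& b,
                   double& phi, std::vector<double>& delta, double& tau,
                   std::vector<double>& d) {
  gamma = std::pow(10.0, th[0]);
  b = -std::pow(10.0, th[1]);
  phi = 0.0;
  tau = 0.0;
  delta.assign(S, 0.0);
  d.assign(S, 0.0);
  if (K == 2) return;
  phi = std::pow(10.0, th[2]);
  if (K == 6) {
    double dl = std::pow(10.0, th[3]);
    double dd = std::pow(10.0, th[5]);
    tau = std::pow(10.0, th[4]);
    for (int s = 1; s < S; s++) { delta[s] = dl; d[s] = dd; }
  } else {
    tau = std::pow(10.0, th[8]);
    // sessions 2..6 (0-based s = 1..5) map to th[3..7] and th[9..13]
    for (int s = 1; s < 6 && s < S; s++) {
      delta[s] = std::pow(10.0, th[2 + s]);
      d[s] = std::pow(10.0, th[8 + s]);
    }
  }
}

// Bernoulli log likelihood of one unit's trials given theta (log10 scale).
// p = a + b2 * (1 - exp(-w)), w = 10^(beta * (log10c - xi) + log10lref),
// clipped to [1e-9, 1 - 1e-9].
static double loglik_core(const double* th, int K, int S,
                          const int* session, const double* within,
                          const double* log10t, const double* log10c,
                          const double* r, int n, double beta,
                          double log10lref, double a, double b2) {
  double gamma, b, phi, tau;
  std::vector<double> delta, d;
  decode(th, K, S, gamma, b, phi, delta, tau, d);
  double s = 0.0;
  for (int i = 0; i < n; i++) {
    int se = session[i] - 1;
    double rel = -tau * within[i];
    if (rel < -d[se]) rel = -d[se];
    double xi = b - gamma * log10t[i] + delta[se] + rel + phi * within[i];
    // degenerate parameters (overflowing magnitudes) make xi undefined;
    // treat the proposal as impossible rather than propagating NaN
    if (ISNAN(xi)) return R_NegInf;
    double w = std::exp(M_LN10 * (beta * (log10c[i] - xi) + log10lref));
    double p = a + b2 * (1.0 - std::exp(-w));
    if (p < 1e-9) p = 1e-9;
    else if (p > 1.0 - 1e-9) p = 1.0 - 1e-9;
    s += std::log(r[i] > 0.5 ? p : 1.0 - p);
  }
  return s;
}

// [[Rcpp::export]]
double loglik_cpp(NumericVector theta, IntegerVector session,
                  NumericVector within, NumericVector log10t,
                  NumericVector log10c, NumericVector r, double beta,
                  double log10lref, double a, double b2, int n_sessions) {
  return loglik_core(theta.begin(), theta.size(), n_sessions,
                     session.begin(), within.begin(), log10t.begin(),
                     log10c.begin(), r.begin(), session.size(), beta,
                     log10lref, a, b2);
}

// One componentwise random-walk Metropolis sweep over theta.
// prior_type: 0 = independent uniform (lower, upper); 1 = independent
// Gaussian N(rho_k, eps2_k); 2 = multivariate Gaussian with mean rho and
// precision Lambda. Returns the updated theta, its log likelihood, and the
// per-component acceptance indicator.
// [[Rcpp::export]]
List mh_update_cpp(NumericVector theta_, double ll, double beta,
                   IntegerVector session, NumericVector within,
                   NumericVector log10t, NumericVector log10c,
                   NumericVector r, double log10lref, double a, double b2,
                   int n_sessions, NumericVector scales, int prior_type,
                   NumericVector lower, NumericVector upper,
                   NumericVector rho, NumericVector eps2,
                   NumericMatrix Lambda) {
  int K = theta_.size();
  NumericVector theta = clone(theta_);
  LogicalVector acc(K);
  int n = session.size();
  for (int k = 0; k < K; k++) {
    double e = norm_rand() * scales[k];
    double cur = theta[k];
    double prop = cur + e;
    double dprior = 0.0;
    if (prior_type == 0) {
      if (prop < lower[k] || prop > upper[k]) continue;
    } else if (prior_type == 1) {
      double c0 = cur - rho[k], c1 = prop - rho[k];
      dprior = (c0 * c0 - c1 * c1) / (2.0 * eps2[k]);
    } else {
      // -1/2 (x-rho)' Lambda (x-rho); change in dimension k only
      double lr = 0.0;
      for (int l = 0; l < K; l++) lr += Lambda(k, l) * (theta[l] - rho[l]);
      dprior = -(e * lr + 0.5 * e * e * Lambda(k, k));
    }
    theta[k] = prop;
    double llp = loglik_core(theta.begin(), K, n_sessions, session.begin(),
                             within.begin(), log10t.begin(), log10c.begin(),
                             r.begin(), n, beta, log10lref, a, b2);
    if (std::log(unif_rand()) < llp - ll + dprior) {
      ll = llp;
      acc[k] = true;
    } else {
      theta[k] = cur;
    }
  }
  return List::create(_["theta"] = theta, _["ll"] = ll, _["acc"] = acc);
}
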