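#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// MCP penalty rho1(|t|; lambda, gamma).  gamma may be R_PosInf (soft
// threshold limit); lambda == 0 collapses the penalty to zero.
static inline double mcp_pen(double t, double lambda, double gamma) {
  double a = std::fabs(t);
  if (lambda <= 0.0) return 0.0;
  if (std::isinf(gamma)) return lambda * a;  // gamma -> Inf limit
  double thr = gamma * lambda;
  if (a <= thr) return lambda * a - a * a / (2.0 * gamma);
  return 0.5 * gamma * lambda * lambda;
}

// One-dimensional objective on the branch carrying the sign of z:
//   f(u) = 0.5*(1+w)*u^2 - (|z|+m)*u + rho1(u)
// where w = lambda2*(sL+sR) and m = lambda2*(sL*|bL| + sR*|bR|).
static inline double f1d(double u, double zm, double w,
                         double lambda1, double gamma) {
  return 0.5 * (1.0 + w) * u * u - zm * u + mcp_pen(u, lambda1, gamma);
}

// Exact minimizer of the one-coordinate SMCP objective.  Candidates are
// the stationary points of each MCP regime plus the regime boundary and
// the origin; because each regime is quadratic (possibly concave when
// gamma*(1+w) <= 1) the global minimum over u >= 0 is attained at one
// of these points.
static double cd_update_scalar(double z, double m, double w,
                               double lambda1, double gamma) {
  double s = (z > 0.0) ? 1.0 : ((z < 0.0) ? -1.0 : 1.0);
  double zm = std::fabs(z) + m;
  if (lambda1 <= 0.0) {
    double u = zm / (1.0 + w);
    return s * u;
  }
  double thr = std::isinf(gamma) ? R_PosInf : gamma * lambda1;
  double best_u = 0.0;
  double best_f = 0.0;  // f(0) = 0
  // inner-regime stationary point (u <= thr)
  double c1 = 1.0 + w - (std::isinf(gamma) ? 0.0 : 1.0 / gamma);
  if (c1 > 0.0) {
    double u1 = (zm - lambda1) / c1;
    if (u1 > 0.0 && u1 <= thr) {
      double f = f1d(u1, zm, w, lambda1, gamma);
      if (f < best_f) { best_f = f; best_u = u1; }
    }
  }
  if (!std::isinf(thr)) {
    // regime boundary (covers the concave c1 <= 0 case)
    double fb = f1d(thr, zm, w, lambda1, gamma);
    if (fb < best_f) { best_f = fb; best_u = thr; }
    // plateau-regime stationary point (u >= thr)
    double u2 = zm / (1.0 + w);
    if (u2 > thr) {
      double f = f1d(u2, zm, w, lambda1, gamma);
      if (f < best_f) { best_f = f; best_u = u2; }
    }
  }
  return s * best_u;
}

// [[Rcpp::export(name = ".cd_update_cpp")]]
double cd_update_cpp(double z, double m, double w,
                     double lambda1, double gamma) {
  return cd_update_scalar(z, m, w, lambda1, gamma);
}

static double objective_cpp(const NumericVector& beta,
                            const NumericVector& z,
                            const NumericVector& Cj,
                            const NumericVector& sigma,
                            double lambda1, double lambda2, double gamma) {
  int p = beta.size();
  double obj = 0.0;
  for (int j = 0; j < p; ++j) {
    obj += Cj[j] - z[j] * beta[j] + 0.5 * beta[j] * beta[j];
    obj += mcp_pen(beta[j], lambda1, gamma);
  }
  for (int j = 0; j + 1 < p; ++j) {
    double d = std::fabs(beta[j]) - std::fabs(beta[j + 1]);
    obj += 0.5 * lambda2 * sigma[j] * d * d;
  }
  return obj;
}

// [[Rcpp::export(name = ".cd_objective_cpp")]]
double cd_objective_cpp(NumericVector beta, NumericVector z,
                        NumericVector Cj, NumericVector sigma,
                        double lambda1, double lambda2, double gamma) {
  return objective_cpp(beta, z, Cj, sigma, lambda1, lambda2, gamma);
}

// Cyclic coordinate descent (ascending SNP index) on the SMCP objective.
// 'active' marks coordinates that are updated; inactive ones stay at
// their initial value (used for monomorphic SNPs and leave-one-out
// refits).  Returns the coefficient vector, the per-sweep objective
// trace, the sweep count and a convergence flag.
// [[Rcpp::export(name = ".cd_fit_cpp")]]
List cd_fit_cpp(NumericVector z, NumericVector Cj, NumericVector sigma,
                double lambda1, double lambda2, double gamma,
                NumericVector beta0, LogicalVector active,
                double tol, int max_sweeps, bool track_obj) {
  int p = z.size();
  NumericVector beta = clone(beta0);
  std::vector<double> trace;
  bool converged = false;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!active[j]) continue;
      double sL = (j > 0) ? sigma[j - 1] : 0.0;
      double sR = (j + 1 < p) ? sigma[j] : 0.0;
      double bL = (j > 0) ? std::fabs(beta[j - 1]) : 0.0;
      double bR = (j + 1 < p) ? std::fabs(beta[j + 1]) : 0.0;
      double w = lambda2 * (sL + sR);
      double m = lambda2 * (sL * bL + sR * bR);
      double bnew = cd_update_scalar(z[j], m, w, lambda1, gamma);
      double d = std::fabs(bnew - beta[j]);
      if (d > max_delta) max_delta = d;
      beta[j] = bnew;
    }
    if (track_obj)
      trace.push_back(objective_cpp(beta, z, Cj, sigma,
                                    lambda1, lambda2, gamma));
    if (max_delta < tol) { converged = true; ++sweep; break; }
  }
  return List::create(_["beta"] = beta,
                      _["objective_trace"] = wrap(trace),
                      _["sweeps"] = sweep,
                      _["converged"] = converged);
}

// Warm-started path over a decreasing tau grid with
// lambda1 = (1 - eta) * tau, lambda2 = eta * tau.
// [[Rcpp::export(name = ".cd_path_cpp")]]
List cd_path_cpp(NumericVector z, NumericVector Cj, NumericVector sigma,
                 NumericVector tau_grid, double eta, double gamma,
                 LogicalVector active, double tol, int max_sweeps) {
  int p = z.size();
  int T = tau_grid.size();
  NumericMatrix betas(p, T);
  IntegerVector sweeps(T);
  LogicalVector conv(T);
  NumericVector beta(p);  // zero start at the null end of the path
  for (int t = 0; t < T; ++t) {
    double tau = tau_grid[t];
    List fit = cd_fit_cpp(z, Cj, sigma, (1.0 - eta) * tau, eta * tau,
                          gamma, beta, active, tol, max_sweeps, false);
    beta = fit["beta"];
    betas(_, t) = beta;
    sweeps[t] = as<int>(fit["sweeps"]);
    conv[t] = as<bool>(fit["converged"]);
  }
  return List::create(_["beta"] = betas, _["sweeps"] = sweeps,
                      _["converged"] = conv);
}
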