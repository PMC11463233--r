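#include <Rcpp.h>
using namespace Rcpp;

// Mutation-selection dynamics over per-agent genomes (w, epsilon, gamma).
//
// Each agent's equilibrium target error follows from the covariance
// recursion of the heterogeneous update rule, whose fixed point depends on
// the group only through two scalars:
//   B = sum_j (1 - w_j)
//   S = sum_j (w_j^2 eps_j^2 + (1 - w_j)^2 gam_j^2 / n)
// The equilibrium variance of the group's average heading is
//   V = S / (n^2 - B^2)          (finite iff B < n, i.e. some w_j > 0)
// and agent i's equilibrium error is
//   sigma_i^2 = w_i^2 eps_i^2 + (1 - w_i)^2 V + (1 - w_i)^2 gam_i^2 / n.
// This closed form lets each mutation trial be evaluated in O(1) using
// running sums, which is what makes full-length runs cheap.

static inline double sigma2_agent(double w, double e, double g,
                                  double V, double n) {
  double u = 1.0 - w;
  return w * w * e * e + u * u * V + u * u * g * g / n;
}

// [[Rcpp::export]]
List evolve_cpp(int n, double k, int steps, double mutation_sd, int thin,
                bool sigma_only,
                NumericVector w0, NumericVector eps0, NumericVector gam0) {
  NumericVector w = clone(w0), eps = clone(eps0), gam = clone(gam0);
  double dn = (double)n;

  double B = 0.0, S = 0.0;
  for (int j = 0; j < n; ++j) {
    B += 1.0 - w[j];
    S += w[j] * w[j] * eps[j] * eps[j] +
         (1.0 - w[j]) * (1.0 - w[j]) * gam[j] * gam[j] / dn;
  }

  int n_snap = steps / thin + 1;
  NumericMatrix snap_w(n_snap, n), snap_e(n_snap, n), snap_g(n_snap, n);
  IntegerVector snap_step(n_snap);
  LogicalVector accepted(steps);
  IntegerVector agent(steps);
  int failures = 0;

  int si = 0;
  snap_step[si] = 0;
  for (int j = 0; j < n; ++j) {
    snap_w(si, j) = w[j]; snap_e(si, j) = eps[j]; snap_g(si, j) = gam[j];
  }
  ++si;

  for (int t = 0; t < steps; ++t) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    agent[t] = i + 1;  // 1-based for R

    // proposal: w on the natural scale (clipped), eps/gam on the log scale
    double wp = w[i] + norm_rand() * mutation_sd;
    if (wp < 0.0) wp = 0.0;
    if (wp > 1.0) wp = 1.0;
    double ep = eps[i] * std::exp(norm_rand() * mutation_sd);
    double gp = gam[i] * std::exp(norm_rand() * mutation_sd);

    double contrib_B = 1.0 - w[i];
    double contrib_S = w[i] * w[i] * eps[i] * eps[i] +
                       contrib_B * contrib_B * gam[i] * gam[i] / dn;

    // current fitness of agent i
    double denom = dn * dn - B * B;
    bool ok_cur = denom > 1e-12;
    double F_cur = -INFINITY;
    if (ok_cur) {
      double sig = std::sqrt(sigma2_agent(w[i], eps[i], gam[i], S / denom, dn));
      F_cur = -sig;
      if (!sigma_only)
        F_cur += -std::pow(eps[i], -k) - std::pow(gam[i], -k);
    }

    // fitness under the proposal (all other agents fixed)
    double Bp = B - contrib_B + (1.0 - wp);
    double Sp = S - contrib_S + wp * wp * ep * ep +
                (1.0 - wp) * (1.0 - wp) * gp * gp / dn;
    double denomp = dn * dn - Bp * Bp;
    bool acc = false;
    if (denomp > 1e-12) {
      double sigp = std::sqrt(sigma2_agent(wp, ep, gp, Sp / denomp, dn));
      double F_new = -sigp;
      if (!sigma_only) F_new += -std::pow(ep, -k) - std::pow(gp, -k);
      acc = F_new > F_cur;
    } else {
      ++failures;  // proposal would destroy the equilibrium; reject
    }

    if (acc) {
      w[i] = wp; eps[i] = ep; gam[i] = gp;
      B = Bp; S = Sp;
    }
    accepted[t] = acc;

    if ((t + 1) % thin == 0) {
      snap_step[si] = t + 1;
      for (int j = 0; j < n; ++j) {
        snap_w(si, j) = w[j]; snap_e(si, j) = eps[j]; snap_g(si, j) = gam[j];
      }
      ++si;
    }
  }

  return List::create(_["snap_step"] = snap_step,
                      _["snap_w"] = snap_w,
                      _["snap_epsilon"] = snap_e,
                      _["snap_gamma"] = snap_g,
                      _["accepted"] = accepted,
                      _["agent"] = agent,
                      _["final_w"] = w,
                      _["final_epsilon"] = eps,
                      _["final_gamma"] = gam,
                      _["failures"] = failures);
}
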