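// Stopping-model likelihoods and the hierarchical MCMC sampler.
//
// Model codes (parameter layout on the natural scale):
//  1 CostOnly:            [b0 bL bH bDraw bCumuCost]                       (5)
//  2 CostEvidence:        [cost(5) bUE bACI bTLE bLD bLC alpha]            (11)
//  3 Cost_Ccond_Evidence: [s1 cost(5) s2 evid(6) alpha psec(3)]            (15)
//  4 Cost_Econd_Evidence: [s1 cost(5) s2 evid(6) alpha psec(2)]            (14)
//  5 Evidence_Ccond_Cost: [s1 evid(6) s2 cost(5) alpha psec(3)]            (15)
//  6 Evidence_Econd_Cost: [s1 evid(6) s2 cost(5) alpha psec(2)]            (14)
// evid block order: [e0 bUnitEvid bAbsCumuInfo bTotalLogEvid bLastDraw bLastCorrect]

#include <Rcpp.h>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double cost_X(const double* b, double j, double c) {
  return b[0] + b[1] * (c == 1.0) + b[2] * (c == 4.0) + b[3] * j + b[4] * c * j;
}

static inline double evid_X(const double* e, double L, double aci,
                            double pd, double pc) {
  return e[0] + e[1] * L + e[2] * aci + e[3] * L * aci + e[4] * pd + e[5] * pc;
}

static inline int n_par_model(int m) {
  switch (m) {
    case 1: return 5;
    case 2: return 11;
    case 3: return 15;
    case 4: return 14;
    case 5: return 15;
    case 6: return 14;
  }
  return -1;
}

static inline double alpha_of(int m, const double* th) {
  if (m == 1) return 1.0;
  if (m == 2) return th[10];
  return th[11];
}

static inline double stop_p(int m, const double* th, int j, double c, double L,
                            double aci, double pd, double pc, int highev) {
  switch (m) {
    case 1:
      return inv_logit(cost_X(th, j, c));
    case 2: {
      double X = cost_X(th, j, c) + th[5] * L + th[6] * aci +
                 th[7] * L * aci + th[8] * pd + th[9] * pc;
      return inv_logit(X);
    }
    case 3: case 4: {
      double p1 = inv_logit(cost_X(th, j, c));
      double p2 = inv_logit(evid_X(th + 5, L, aci, pd, pc));
      double ps = (m == 3)
        ? th[12 + (c == 1.0 ? 1 : (c == 4.0 ? 2 : 0))]
        : th[12 + (highev ? 1 : 0)];
      return p1 + (1.0 - p1) * ps * p2;
    }
    case 5: case 6: {
      double p1 = inv_logit(evid_X(th, L, aci, pd, pc));
      double p2 = inv_logit(cost_X(th + 6, j, c));
      double ps = (m == 5)
        ? th[12 + (c == 1.0 ? 1 : (c == 4.0 ? 2 : 0))]
        : th[12 + (highev ? 1 : 0)];
      return p1 + (1.0 - p1) * ps * p2;
    }
  }
  return NA_REAL;
}

// Log-likelihood of one trial's stopping time (hazard at j = 0..19, forced
// stop at 20). s points at the 20 signed stimuli of the trial.
static double trial_ll(int m, const double* th, int n, double c, double L,
                       double pd, double pc, const int* s, int highev) {
  double alpha = alpha_of(m, th);
  double ci = 0.0, ll = 0.0;
  int jmax = (n < 20) ? n : 19;
  for (int j = 0; j <= jmax; ++j) {
    double p = stop_p(m, th, j, c, L, std::fabs(ci), pd, pc, highev);
    if (j == n && n < 20) return ll + std::log(p);
    ll += std::log1p(-p);
    ci = alpha * ci + s[j];
  }
  return ll;
}

struct FitData {
  int n_trials, n_children;
  IntegerVector child, n, highev, child_start, child_end;
  NumericVector c, L, pd, pc;
  IntegerMatrix S;  // n_trials x 20
  explicit FitData(List data)
    : child(as<IntegerVector>(data["child"])),
      n(as<IntegerVector>(data["n"])),
      highev(as<IntegerVector>(data["highev"])),
      child_start(as<IntegerVector>(data["child_start"])),
      child_end(as<IntegerVector>(data["child_end"])),
      c(as<NumericVector>(data["c"])),
      L(as<NumericVector>(data["L"])),
      pd(as<NumericVector>(data["prev_draw"])),
      pc(as<NumericVector>(data["prev_correct"])),
      S(as<IntegerMatrix>(data["S"])) {
    n_trials = child.size();
    n_children = child_start.size();
  }
};

static double child_ll(int m, const double* th, const FitData& d, int c_idx,
                       std::vector<int>& sbuf) {
  double ll = 0.0;
  for (int t = d.child_start[c_idx]; t <= d.child_end[c_idx]; ++t) {
    for (int k = 0; k < 20; ++k) sbuf[k] = d.S(t, k);
    ll += trial_ll(m, th, d.n[t], d.c[t], d.L[t], d.pd[t], d.pc[t],
                   sbuf.data(), d.highev[t]);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_pointwise_ll_one(int model, NumericMatrix theta_nat,
                                   List data) {
  FitData d(data);
  int P = n_par_model(model);
  if (theta_nat.ncol() != P || theta_nat.nrow() != d.n_children)
    stop("theta_nat has wrong dimensions");
  NumericVector out(d.n_trials);
  std::vector<double> th(P);
  std::vector<int> sbuf(20);
  for (int t = 0; t < d.n_trials; ++t) {
    int ci = d.child[t];
    for (int p = 0; p < P; ++p) th[p] = theta_nat(ci, p);
    for (int k = 0; k < 20; ++k) sbuf[k] = d.S(t, k);
    out[t] = trial_ll(model, th.data(), d.n[t], d.c[t], d.L[t], d.pd[t],
                      d.pc[t], sbuf.data(), d.highev[t]);
  }
  return out;
}

// Pointwise log-likelihood over posterior draws: theta_draws is
// n_draws x (n_children * P), children varying fastest within a parameter
// block? -- layout: column index = p * n_children + child.
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_ll_draws(int model, NumericMatrix theta_draws,
                                     List data) {
  FitData d(data);
  int P = n_par_model(model);
  int S = theta_draws.nrow();
  if (theta_draws.ncol() != P * d.n_children)
    stop("theta_draws has wrong number of columns");
  NumericMatrix out(S, d.n_trials);
  std::vector<double> th(P);
  std::vector<int> sbuf(20);
  for (int s = 0; s < S; ++s) {
    for (int t = 0; t < d.n_trials; ++t) {
      int ci = d.child[t];
      for (int p = 0; p < P; ++p)
        th[p] = theta_draws(s, p * d.n_children + ci);
      for (int k = 0; k < 20; ++k) sbuf[k] = d.S(t, k);
      out(s, t) = trial_ll(model, th.data(), d.n[t], d.c[t], d.L[t], d.pd[t],
                           d.pc[t], sbuf.data(), d.highev[t]);
    }
  }
  return out;
}

// Average analytic stopping distribution over posterior draws, per trial.
// Returns n_trials x 21 matrix of P(N = n).
// [[Rcpp::export]]
NumericMatrix cpp_predictive_dist(int model, NumericMatrix theta_draws,
                                  List data) {
  FitData d(data);
  int P = n_par_model(model);
  int S = theta_draws.nrow();
  NumericMatrix out(d.n_trials, 21);
  std::vector<double> th(P);
  for (int s = 0; s < S; ++s) {
    for (int t = 0; t < d.n_trials; ++t) {
      int ci = d.child[t];
      for (int p = 0; p < P; ++p)
        th[p] = theta_draws(s, p * d.n_children + ci);
      double alpha = alpha_of(model, th.data());
      double ciacc = 0.0, surv = 1.0;
      for (int j = 0; j < 20; ++j) {
        double p = stop_p(model, th.data(), j, d.c[t], d.L[t],
                          std::fabs(ciacc), d.pd[t], d.pc[t], d.highev[t]);
        out(t, j) += surv * p;
        surv *= (1.0 - p);
        ciacc = alpha * ciacc + d.S(t, j);
      }
      out(t, 20) += surv;
    }
  }
  for (int t = 0; t < d.n_trials; ++t)
    for (int j = 0; j <= 20; ++j) out(t, j) /= S;
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: non-centered parameterization
//   theta_nat[c,p] = transform_p(mu[p] + sigma[p] * z[c,p]),
// transform_p = identity or inverse-logit (is_logit flag). Blockwise adaptive
// random-walk Metropolis: one block per child (z rows) and two global blocks
// (mu, log sigma), with Robbins-Monro scale adaptation and running-variance
// preconditioning during warm-up.

// Running mean and covariance (Welford) with a Cholesky factor of the
// regularised covariance, refreshed periodically during warm-up.
struct RunningCov {
  int P;
  long n = 0;
  std::vector<double> mean, cov, chol, base_diag;
  RunningCov(int dim, const std::vector<double>& base)
    : P(dim), mean(dim, 0.0), cov(dim * dim, 0.0), chol(dim * dim, 0.0),
      base_diag(base) {
    refresh();
  }
  void update(const std::vector<double>& x) {
    ++n;
    std::vector<double> d(P);
    for (int i = 0; i < P; ++i) {
      d[i] = x[i] - mean[i];
      mean[i] += d[i] / n;
    }
    for (int i = 0; i < P; ++i)
      for (int j = 0; j <= i; ++j) {
        double upd = d[i] * (x[j] - mean[j]);
        cov[i * P + j] += upd;
        if (i != j) cov[j * P + i] += upd;
      }
  }
  // Cholesky of (S_n + eps * diag(base)); falls back to diagonal.
  void refresh() {
    std::vector<double> A(P * P, 0.0);
    double denom = (n > 1) ? (double)(n - 1) : 1.0;
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < P; ++j)
        A[i * P + j] = (n > 1 ? cov[i * P + j] / denom : 0.0);
    for (int i = 0; i < P; ++i)
      A[i * P + i] += 0.05 * base_diag[i] + 1e-10;
    std::fill(chol.begin(), chol.end(), 0.0);
    for (int i = 0; i < P; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = A[i * P + j];
        for (int k = 0; k < j; ++k) s -= chol[i * P + k] * chol[j * P + k];
        if (i == j) {
          chol[i * P + i] = std::sqrt(std::max(s, 1e-12));
        } else {
          chol[i * P + j] = s / chol[j * P + j];
        }
      }
    }
  }
  void propose(const std::vector<double>& x, double scale,
               std::vector<double>& out) const {
    std::vector<double> eta(P);
    for (int i = 0; i < P; ++i) eta[i] = norm_rand();
    for (int i = 0; i < P; ++i) {
      double s = 0.0;
      for (int k = 0; k <= i; ++k) s += chol[i * P + k] * eta[k];
      out[i] = x[i] + scale * s;
    }
  }
};

// [[Rcpp::export]]
List cpp_fit_chain(int model, List data, List prior, int n_warmup, int n_iter,
                   NumericVector init_scale) {
  FitData d(data);
  int P = n_par_model(model);
  int C = d.n_children;
  NumericVector mu_loc = prior["mu_loc"], mu_scale = prior["mu_scale"],
                sd_scale = prior["sd_scale"];
  IntegerVector is_logit = prior["is_logit"];
  if (mu_loc.size() != P) stop("prior dimension mismatch");

  std::vector<double> mu(P), ls(P);
  std::vector<std::vector<double>> z(C, std::vector<double>(P));
  for (int p = 0; p < P; ++p) {
    mu[p] = mu_loc[p] + 0.1 * mu_scale[p] * norm_rand();
    ls[p] = std::log(0.5) + 0.1 * norm_rand();
  }
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < P; ++p) z[c][p] = 0.2 * norm_rand();

  std::vector<int> sbuf(20);
  std::vector<double> th(P);

  auto nat_theta = [&](int c, std::vector<double>& out) {
    for (int p = 0; p < P; ++p) {
      double v = mu[p] + std::exp(ls[p]) * z[c][p];
      out[p] = is_logit[p] ? inv_logit(v) : v;
    }
  };
  auto child_loglik = [&](int c) {
    nat_theta(c, th);
    return child_ll(model, th.data(), d, c, sbuf);
  };

  std::vector<double> cur_ll(C);
  for (int c = 0; c < C; ++c) cur_ll[c] = child_loglik(c);

  auto z_logprior = [&](const std::vector<double>& zc) {
    double s = 0.0;
    for (int p = 0; p < P; ++p) s += -0.5 * zc[p] * zc[p];
    return s;
  };
  auto mu_logprior = [&]() {
    double s = 0.0;
    for (int p = 0; p < P; ++p) {
      double r = (mu[p] - mu_loc[p]) / mu_scale[p];
      s += -0.5 * r * r;
    }
    return s;
  };
  // half-normal on sigma with log-scale Jacobian
  auto ls_logprior = [&]() {
    double s = 0.0;
    for (int p = 0; p < P; ++p) {
      double sig = std::exp(ls[p]);
      double r = sig / sd_scale[p];
      s += -0.5 * r * r + ls[p];
    }
    return s;
  };

  std::vector<double> base_z(P, 0.2), base_ls(P, 0.04), base_mu(P);
  for (int p = 0; p < P; ++p) base_mu[p] = init_scale[p] * init_scale[p];
  std::vector<double> lam_z(C, std::log(2.38 / std::sqrt((double)P)));
  double lam_mu = std::log(1.0), lam_ls = std::log(1.0);
  std::vector<RunningCov> rc_z(C, RunningCov(P, base_z));
  RunningCov rc_mu(P, base_mu), rc_ls(P, base_ls);
  // per-parameter scales for the interweaving moves
  std::vector<double> lam_tr(P, std::log(0.2)), lam_sc(P, std::log(0.3));
  const double target = 0.25;

  int total = n_warmup + n_iter;
  NumericMatrix draws_mu(n_iter, P), draws_sig(n_iter, P),
                draws_theta(n_iter, C * P);
  double acc_z = 0.0, acc_mu = 0.0, acc_ls = 0.0;
  long n_z_prop = 0, n_glob_prop = 0;

  std::vector<double> zprop(P), old_block(P), new_lls(C);

  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    double gam = warm ? 1.0 / std::pow(it + 2.0, 0.55) : 0.0;

    // --- child blocks ---
    for (int c = 0; c < C; ++c) {
      rc_z[c].propose(z[c], std::exp(lam_z[c]), zprop);
      std::swap(z[c], zprop);
      double new_ll = child_loglik(c);
      std::swap(z[c], zprop);
      double lr = new_ll + z_logprior(zprop) - cur_ll[c] - z_logprior(z[c]);
      double a = std::min(1.0, std::exp(lr));
      if (unif_rand() < a) {
        z[c] = zprop;
        cur_ll[c] = new_ll;
      }
      if (warm) {
        lam_z[c] += gam * (a - target);
        if (it > 25) rc_z[c].update(z[c]);
      } else { acc_z += a; ++n_z_prop; }
    }

    // --- mu block ---
    {
      double tot_ll = 0.0;
      for (int c = 0; c < C; ++c) tot_ll += cur_ll[c];
      old_block = mu;
      double old_lp = mu_logprior();
      rc_mu.propose(old_block, std::exp(lam_mu), mu);
      double new_ll = 0.0;
      for (int c = 0; c < C; ++c) { new_lls[c] = child_loglik(c); new_ll += new_lls[c]; }
      double lr = new_ll + mu_logprior() - tot_ll - old_lp;
      double a = std::min(1.0, std::exp(lr));
      if (unif_rand() < a) {
        cur_ll = new_lls;
      } else {
        mu = old_block;
      }
      if (warm) {
        lam_mu += gam * (a - target);
        if (it > 25) rc_mu.update(mu);
      } else { acc_mu += a; }
    }

    // --- log-sigma block ---
    {
      double tot_ll = 0.0;
      for (int c = 0; c < C; ++c) tot_ll += cur_ll[c];
      old_block = ls;
      double old_lp = ls_logprior();
      rc_ls.propose(old_block, std::exp(lam_ls), ls);
      double new_ll = 0.0;
      for (int c = 0; c < C; ++c) { new_lls[c] = child_loglik(c); new_ll += new_lls[c]; }
      double lr = new_ll + ls_logprior() - tot_ll - old_lp;
      double a = std::min(1.0, std::exp(lr));
      if (unif_rand() < a) {
        cur_ll = new_lls;
      } else {
        ls = old_block;
      }
      if (warm) {
        lam_ls += gam * (a - target);
        if (it > 25) rc_ls.update(ls);
      } else { acc_ls += a; ++n_glob_prop; }
    }

    // --- interweaving moves (likelihood-invariant, prior-only MH) ---
    // Cheap (no likelihood evaluation), so swept several times per iteration.
    for (int sweep = 0; sweep < 4; ++sweep) {
    // Translation: mu_p -> mu_p + delta with z_.p -> z_.p - delta/sigma_p
    // keeps every child's theta fixed.
    for (int p = 0; p < P; ++p) {
      double delta = std::exp(lam_tr[p]) * norm_rand();
      double mu_new = mu[p] + delta;
      double shift = delta / std::exp(ls[p]);
      double lr = 0.0;
      {
        double r0 = (mu[p] - mu_loc[p]) / mu_scale[p];
        double r1 = (mu_new - mu_loc[p]) / mu_scale[p];
        lr += 0.5 * r0 * r0 - 0.5 * r1 * r1;
      }
      for (int c = 0; c < C; ++c) {
        double z0 = z[c][p], z1 = z0 - shift;
        lr += 0.5 * z0 * z0 - 0.5 * z1 * z1;
      }
      double a = std::min(1.0, std::exp(lr));
      if (unif_rand() < a) {
        mu[p] = mu_new;
        for (int c = 0; c < C; ++c) z[c][p] -= shift;
      }
      if (warm) lam_tr[p] += gam * (a - target);
    }
    // Rescale: sigma_p -> sigma_p e^u with z_.p -> z_.p e^-u (theta fixed);
    // Jacobian of the z scaling contributes -C u.
    for (int p = 0; p < P; ++p) {
      double u = std::exp(lam_sc[p]) * norm_rand();
      double ls_new = ls[p] + u;
      double sig0 = std::exp(ls[p]), sig1 = std::exp(ls_new);
      double lr = -C * u;
      {
        double r0 = sig0 / sd_scale[p], r1 = sig1 / sd_scale[p];
        lr += (-0.5 * r1 * r1 + ls_new) - (-0.5 * r0 * r0 + ls[p]);
      }
      double eu = std::exp(-u);
      for (int c = 0; c < C; ++c) {
        double z0 = z[c][p], z1 = z0 * eu;
        lr += 0.5 * z0 * z0 - 0.5 * z1 * z1;
      }
      double a = std::min(1.0, std::exp(lr));
      if (unif_rand() < a) {
        ls[p] = ls_new;
        for (int c = 0; c < C; ++c) z[c][p] *= eu;
      }
      if (warm) lam_sc[p] += gam * (a - target);
    }
    }  // interweaving sweeps

    if (warm && it > 25 && it % 25 == 0) {
      for (int c = 0; c < C; ++c) rc_z[c].refresh();
      rc_mu.refresh();
      rc_ls.refresh();
    }

    if (!warm) {
      int row = it - n_warmup;
      for (int p = 0; p < P; ++p) {
        draws_mu(row, p) = mu[p];
        draws_sig(row, p) = std::exp(ls[p]);
      }
      for (int c = 0; c < C; ++c) {
        nat_theta(c, th);
        for (int p = 0; p < P; ++p)
          draws_theta(row, p * C + c) = th[p];
      }
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["mu"] = draws_mu, _["sigma"] = draws_sig, _["theta"] = draws_theta,
    _["accept"] = List::create(
      _["child"] = n_z_prop ? acc_z / n_z_prop : NA_REAL,
      _["mu"] = n_glob_prop ? acc_mu / n_glob_prop : NA_REAL,
      _["sigma"] = n_glob_prop ? acc_ls / n_glob_prop : NA_REAL));
}
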