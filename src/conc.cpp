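#include <Rcpp.h>
using namespace Rcpp;

// Two-compartment disposition fed by one first-order absorption path.
// u: time since the path started absorbing; A: amount entering the depot.
// Handles the removable singularity ka == lambda by its analytic limit.
static inline double one_path(double u, double ka, double A, double V1,
                              double k21, double l1, double l2) {
  if (u <= 0.0 || A <= 0.0) return 0.0;
  const double scale = ka * A / V1;
  const double tol = 1e-8;
  double val;
  if (std::abs(ka - l1) < tol * l1) {
    const double d = l2 - l1;
    val = std::exp(-l1 * u) * (u * (k21 - l1) / d - (k21 - l2) / (d * d)) +
          (k21 - l2) / ((ka - l2) * (l1 - l2)) * std::exp(-l2 * u);
  } else if (std::abs(ka - l2) < tol * l2) {
    const double d = l1 - l2;
    val = std::exp(-l2 * u) * (u * (k21 - l2) / d - (k21 - l1) / (d * d)) +
          (k21 - l1) / ((ka - l1) * (l2 - l1)) * std::exp(-l1 * u);
  } else {
    const double c1 = (k21 - l1) / ((ka - l1) * (l2 - l1));
    const double c2 = (k21 - l2) / ((ka - l2) * (l1 - l2));
    const double c3 = (k21 - ka) / ((l1 - ka) * (l2 - ka));
    val = c1 * std::exp(-l1 * u) + c2 * std::exp(-l2 * u) +
          c3 * std::exp(-ka * u);
  }
  return scale * val;
}

// Plasma concentration of the dual-absorption two-compartment model,
// elementwise over observation rows. Every argument is either length n
// or length 1 (recycled).
// [[Rcpp::export(name = ".conc_rows_cpp")]]
NumericVector conc_rows_cpp(NumericVector t, NumericVector ka1,
                            NumericVector ka2, NumericVector F1,
                            NumericVector tlag2, NumericVector CL,
                            NumericVector V1, NumericVector Q,
                            NumericVector V2, NumericVector dose) {
  const R_xlen_t n = t.size();
  NumericVector out(n);
  const bool s1 = ka1.size() == 1, s2 = ka2.size() == 1, s3 = F1.size() == 1,
             s4 = tlag2.size() == 1, s5 = CL.size() == 1, s6 = V1.size() == 1,
             s7 = Q.size() == 1, s8 = V2.size() == 1, s9 = dose.size() == 1;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double ti = t[i];
    const double a1 = ka1[s1 ? 0 : i], a2 = ka2[s2 ? 0 : i];
    const double f1 = F1[s3 ? 0 : i], tl = tlag2[s4 ? 0 : i];
    const double cl = CL[s5 ? 0 : i], v1 = V1[s6 ? 0 : i];
    const double q = Q[s7 ? 0 : i], v2 = V2[s8 ? 0 : i];
    const double D = dose[s9 ? 0 : i];
    const double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
    const double s = k10 + k12 + k21;
    const double l1 = 0.5 * (s + std::sqrt(s * s - 4.0 * k10 * k21));
    const double l2 = (k10 * k21) / l1;
    out[i] = one_path(ti, a1, f1 * D, v1, k21, l1, l2) +
             one_path(ti - tl, a2, (1.0 - f1) * D, v1, k21, l1, l2);
  }
  return out;
}

// subject-level constants of the concentration solution, computed once
// per parameter vector (they do not depend on the observation time)
struct SubjPK {
  double ka1, ka2, F1, tl, V1, k21, l1, l2;
};

// phi: one subject's transformed parameters in canonical order
// (ka1, ka2, F1, tlag2, CL, V1, Q, V2); log scale, logit for F1
static inline SubjPK prep_subject(const double *phi) {
  SubjPK s;
  s.ka1 = std::exp(phi[0]);
  s.ka2 = std::exp(phi[1]);
  s.F1 = 1.0 / (1.0 + std::exp(-phi[2]));
  s.tl = std::exp(phi[3]);
  const double cl = std::exp(phi[4]);
  s.V1 = std::exp(phi[5]);
  const double q = std::exp(phi[6]), v2 = std::exp(phi[7]);
  const double k10 = cl / s.V1, k12 = q / s.V1;
  s.k21 = q / v2;
  const double sum = k10 + k12 + s.k21;
  s.l1 = 0.5 * (sum + std::sqrt(sum * sum - 4.0 * k10 * s.k21));
  s.l2 = (k10 * s.k21) / s.l1;
  return s;
}

static inline double conc_at(const SubjPK &s, double t, double dose) {
  return one_path(t, s.ka1, s.F1 * dose, s.V1, s.k21, s.l1, s.l2) +
         one_path(t - s.tl, s.ka2, (1.0 - s.F1) * dose, s.V1, s.k21,
                  s.l1, s.l2);
}

static inline double err_sd(double f, int model, double a, double b) {
  double s = model == 0 ? b * f : (model == 1 ? a : a + b * f);
  return s > 1e-12 ? s : 1e-12;
}

static inline double subj_ll(const double *phi, const double *t,
                             const double *dv, const double *dose,
                             int n, int model, double a, double b) {
  static const double LOG2PI = 1.8378770664093454836;
  const SubjPK sp = prep_subject(phi);
  double ll = 0.0;
  for (int r = 0; r < n; ++r) {
    const double f = conc_at(sp, t[r], dose[r]);
    const double s = err_sd(f, model, a, b);
    const double z = (dv[r] - f) / s;
    ll += -0.5 * (LOG2PI + z * z) - std::log(s);
  }
  return std::isfinite(ll) ? ll : -std::numeric_limits<double>::infinity();
}

// One SAEM E-step iteration: componentwise Metropolis-within-Gibbs over
// the individual transformed parameters, a random-walk kernel followed by
// an independence kernel drawn from the current population distribution,
// repeated n_sweep times. Modifies phi and ll in place (R-side copies are
// made by the caller); uses R's RNG so runs are seed-reproducible.
// Returns acceptance rates of the random-walk kernel per parameter.
// [[Rcpp::export(name = ".mh_estep_cpp")]]
NumericVector mh_estep_cpp(NumericMatrix phi, NumericVector ll,
                           NumericMatrix phi_typ, NumericVector omega,
                           NumericVector prop_sd, IntegerVector iiv_idx,
                           NumericVector time, NumericVector dv,
                           NumericVector dose, IntegerVector obs_start,
                           IntegerVector obs_len, int err_model,
                           double a, double b, int n_sweep) {
  const int n = phi.nrow();
  const int d = iiv_idx.size();
  NumericVector acc_rate(d);
  double phi_i[8];
  for (int sw = 0; sw < n_sweep; ++sw) {
    for (int jj = 0; jj < d; ++jj) {
      const int j = iiv_idx[jj] - 1;
      const double om = omega[j];
      // random-walk kernel
      int nacc = 0;
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < 8; ++c) phi_i[c] = phi(i, c);
        const double cur = phi_i[j];
        const double prop = cur + prop_sd[j] * R::norm_rand();
        phi_i[j] = prop;
        const double llp = subj_ll(phi_i, &time[obs_start[i] - 1],
                                   &dv[obs_start[i] - 1],
                                   &dose[obs_start[i] - 1], obs_len[i],
                                   err_model, a, b);
        const double dprior =
            R::dnorm(prop, phi_typ(i, j), om, 1) -
            R::dnorm(cur, phi_typ(i, j), om, 1);
        if (std::log(R::unif_rand()) < (llp - ll[i]) + dprior) {
          phi(i, j) = prop;
          ll[i] = llp;
          ++nacc;
        }
      }
      if (sw == 0) acc_rate[jj] = (double)nacc / n;
      // independence kernel from the population distribution
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < 8; ++c) phi_i[c] = phi(i, c);
        const double prop = phi_typ(i, j) + om * R::norm_rand();
        phi_i[j] = prop;
        const double llp = subj_ll(phi_i, &time[obs_start[i] - 1],
                                   &dv[obs_start[i] - 1],
                                   &dose[obs_start[i] - 1], obs_len[i],
                                   err_model, a, b);
        if (std::log(R::unif_rand()) < (llp - ll[i])) {
          phi(i, j) = prop;
          ll[i] = llp;
        }
      }
    }
  }
  return acc_rate;
}

// Importance-sampling log-weights for the marginal likelihood. The
// proposal is multivariate t(df) per subject with location eta_mean and
// scale factor L (lower Cholesky, n x d x d flattened subject-fastest).
// Returns an n x nsim matrix of log weights; the caller log-sum-exps.
// [[Rcpp::export(name = ".is_logw_cpp")]]
NumericMatrix is_logw_cpp(NumericMatrix phi_typ, NumericMatrix eta_mean,
                          NumericVector Lflat, NumericVector omega,
                          IntegerVector iiv_idx, double df, int nsim,
                          NumericVector time, NumericVector dv,
                          NumericVector dose, IntegerVector obs_start,
                          IntegerVector obs_len, int err_model,
                          double a, double b) {
  const int n = phi_typ.nrow();
  const int d = iiv_idx.size();
  NumericMatrix logw(n, nsim);
  const double lgconst = R::lgammafn((df + d) / 2.0) -
                         R::lgammafn(df / 2.0) - d / 2.0 * std::log(df * M_PI);
  std::vector<double> z(d), eta(d);
  double phi_i[8];
  // log-determinants of the Cholesky factors
  std::vector<double> logdetL(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c)
      logdetL[i] += std::log(Lflat[i + n * (c + d * c)]);
  for (int s = 0; s < nsim; ++s) {
    for (int i = 0; i < n; ++i) {
      double z2 = 0.0;
      for (int c = 0; c < d; ++c) {
        z[c] = R::norm_rand();
        z2 += z[c] * z[c];
      }
      const double g = std::sqrt(R::rchisq(df) / df);
      double lprior = 0.0;
      for (int c = 0; c < 8; ++c) phi_i[c] = phi_typ(i, c);
      for (int c = 0; c < d; ++c) {
        double acc = 0.0;
        for (int e = 0; e <= c; ++e) acc += Lflat[i + n * (c + d * e)] * z[e];
        eta[c] = eta_mean(i, c) + acc / g;
        const int j = iiv_idx[c] - 1;
        phi_i[j] += eta[c];
        lprior += R::dnorm(eta[c], 0.0, omega[j], 1);
      }
      const double llo = subj_ll(phi_i, &time[obs_start[i] - 1],
                                 &dv[obs_start[i] - 1],
                                 &dose[obs_start[i] - 1], obs_len[i],
                                 err_model, a, b);
      const double lq = lgconst - logdetL[i] -
                        (df + d) / 2.0 * std::log1p(z2 / (g * g) / df);
      logw(i, s) = llo + lprior - lq;
    }
  }
  return logw;
}

// Per-group sums of Gaussian log-densities: the per-subject conditional
// log-likelihood for grouped observation rows. idx is 1-based and must
// map every row to a group in 1..ngroup.
// [[Rcpp::export(name = ".ll_by_group_cpp")]]
NumericVector ll_by_group_cpp(NumericVector y, NumericVector f,
                              NumericVector sd, IntegerVector idx,
                              int ngroup) {
  static const double LOG2PI = 1.8378770664093454836;
  NumericVector out(ngroup);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = sd[i] > 1e-12 ? sd[i] : 1e-12;
    const double z = (y[i] - f[i]) / s;
    out[idx[i] - 1] += -0.5 * (LOG2PI + z * z) - std::log(s);
  }
  return out;
}
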