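#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical plume model
//
//   log y_i ~ Normal(log mu_i, 1/tau_y)
//   mu_i    = sum_j beta_j * exp(-alpha_{g(j)} * K_{i,j})
//   beta_j  = theta * S_j * exp(nu_j),   nu_j ~ Normal(0, 1/tau_nu)
//
// K is log(d) for the power kernel (z = beta * d^-alpha) and d itself for
// the exponential kernel (z = beta * exp(-alpha d)); the update algebra is
// identical in either case.
//
// alpha_g and theta are updated by random-walk Metropolis on the log scale
// (both are positive); nu_j by random-walk Metropolis on the natural scale;
// tau_y and tau_nu are conjugate gamma draws. Proposal scales adapt toward
// a 0.44 acceptance rate in batches of 50 during burn-in only, so the
// post-burn-in kernel satisfies detailed balance.

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
List mcmc_plume(NumericVector logy,      // n training observations, log scale
                NumericMatrix K,         // n x m kernel distance matrix
                NumericVector S,         // m relative loadings (max = 1)
                IntegerVector agroup,    // m, 1-based alpha-group index
                List priors, List init,
                int n_iter, int n_burn, int thin,
                bool use_likelihood, bool update_nu) {
  const int n = logy.size();
  const int m = S.size();
  int G = 0;
  for (int j = 0; j < m; ++j) G = std::max(G, agroup[j]);

  const double a_ty = priors["tau_y_shape"], b_ty = priors["tau_y_rate"];
  const double a_tn = priors["tau_nu_shape"], b_tn = priors["tau_nu_rate"];
  const double a_al = priors["alpha_shape"], b_al = priors["alpha_rate"];
  const double th_m = priors["theta_logmean"], th_s = priors["theta_logsd"];

  NumericVector alpha = clone(as<NumericVector>(init["alpha"])); // length G
  double theta = init["theta"];
  NumericVector nu = clone(as<NumericVector>(init["nu"]));       // length m
  double tau_y = init["tau_y"], tau_nu = init["tau_nu"];

  // current kernel weights, betas, means and residual sum of squares
  NumericMatrix W(n, m);
  NumericVector beta(m), mu(n);
  for (int j = 0; j < m; ++j) {
    beta[j] = theta * S[j] * std::exp(nu[j]);
    const double a = alpha[agroup[j] - 1];
    for (int i = 0; i < n; ++i) W(i, j) = std::exp(-a * K(i, j));
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += beta[j] * W(i, j);
    mu[i] = s;
  }
  double ssr = 0.0;
  for (int i = 0; i < n; ++i) ssr += sq(logy[i] - std::log(mu[i]));
  if (!R_finite(ssr))
    stop("non-finite residuals at the initial state; check inputs/inits");

  // adaptive proposal log-scales: G alpha blocks, theta, m nu blocks
  const int nblk = G + 1 + m;
  std::vector<double> lsc(nblk, std::log(0.1));
  std::vector<int> acc(nblk, 0), att(nblk, 0);
  int batch = 0;

  const int n_keep = (n_iter - n_burn) / thin;
  const int npar = G + 1 + m + 2;
  NumericMatrix draws(n_keep, npar);
  NumericVector dev(n_keep);
  int row = 0;

  NumericVector Wprop(n);  // scratch column

  for (int it = 1; it <= n_iter; ++it) {
    // -- alpha blocks ------------------------------------------------------
    // theta is integrated out analytically in the acceptance ratio (its
    // log has a Gaussian conditional), then redrawn below: a partially
    // collapsed blocked (alpha, theta) update that removes the strong
    // alpha-theta posterior correlation from the alpha chain
    const double lt_cur = std::log(theta);
    // marginal (over log-theta) -2*loglik up to constants, from residual
    // sums of r_i = logy_i - (log mu_i - log theta) - theta_logmean
    auto marg = [&](double sr, double sr2) {
      const double denom = 1.0 + n * tau_y * sq(th_s);
      return -0.5 * (tau_y * sr2 - sq(tau_y * th_s) * sq(sr) / denom);
    };
    for (int g = 0; g < G; ++g) {
      const int blk = g;
      att[blk]++;
      const double la = std::log(alpha[g]);
      const double lap = la + std::exp(lsc[blk]) * R::norm_rand();
      const double ap = std::exp(lap);
      // proposed mu touching only columns in group g (likelihood mode
      // only: prior sampling needs no field bookkeeping and must not be
      // gated on it)
      double ssr_p = 0.0, sr = 0.0, sr2 = 0.0, sr_p = 0.0, sr2_p = 0.0;
      bool ok = true;
      std::vector<double> mu_p;
      if (use_likelihood) {
        mu_p.assign(mu.begin(), mu.end());
        for (int j = 0; j < m; ++j) {
          if (agroup[j] - 1 != g) continue;
          for (int i = 0; i < n; ++i) {
            const double w = std::exp(-ap * K(i, j));
            mu_p[i] += beta[j] * (w - W(i, j));
          }
        }
        for (int i = 0; i < n; ++i) {
          if (mu_p[i] <= 0.0) { ok = false; break; }
          ssr_p += sq(logy[i] - std::log(mu_p[i]));
          const double rc = logy[i] - (std::log(mu[i]) - lt_cur) - th_m;
          const double rp = logy[i] - (std::log(mu_p[i]) - lt_cur) - th_m;
          sr += rc; sr2 += sq(rc); sr_p += rp; sr2_p += sq(rp);
        }
        ok = ok && R_finite(ssr_p);
      }
      if (ok) {
        double lr = R::dgamma(ap, a_al, 1.0 / b_al, 1) -
                    R::dgamma(alpha[g], a_al, 1.0 / b_al, 1) + (lap - la);
        if (use_likelihood) lr += marg(sr_p, sr2_p) - marg(sr, sr2);
        if (std::log(R::unif_rand()) < lr) {
          alpha[g] = ap;
          if (use_likelihood) {
            for (int j = 0; j < m; ++j)
              if (agroup[j] - 1 == g)
                for (int i = 0; i < n; ++i)
                  W(i, j) = std::exp(-ap * K(i, j));
            for (int i = 0; i < n; ++i) mu[i] = mu_p[i];
            ssr = ssr_p;
          }
          acc[blk]++;
        }
      }
    }

    // -- theta: conjugate normal draw for log(theta) ----------------------
    // log y_i = log(theta) + log(mu_i/theta) + e_i, so given the rest the
    // full conditional of log(theta) is Gaussian
    {
      const double lt = std::log(theta);
      double prec = 1.0 / sq(th_s), mn = th_m / sq(th_s);
      if (use_likelihood) {
        prec += n * tau_y;
        for (int i = 0; i < n; ++i)
          mn += tau_y * (logy[i] - (std::log(mu[i]) - lt));
      }
      const double ltp = mn / prec + R::norm_rand() / std::sqrt(prec);
      const double ratio = std::exp(ltp - lt);
      theta = std::exp(ltp);
      if (use_likelihood) {
        ssr = 0.0;
        for (int i = 0; i < n; ++i) {
          mu[i] *= ratio;
          ssr += sq(logy[i] - std::log(mu[i]));
        }
        for (int j = 0; j < m; ++j) beta[j] *= ratio;
      }
    }

    // -- nu_j --------------------------------------------------------------
    if (update_nu) {
      for (int j = 0; j < m; ++j) {
        const int blk = G + 1 + j;
        att[blk]++;
        const double np = nu[j] + std::exp(lsc[blk]) * R::norm_rand();
        const double bp = theta * S[j] * std::exp(np);
        double ssr_p = 0.0;
        bool ok = true;
        if (use_likelihood) {
          for (int i = 0; i < n; ++i) {
            const double mp = mu[i] + (bp - beta[j]) * W(i, j);
            if (mp <= 0.0) { ok = false; break; }
            Wprop[i] = mp;
            ssr_p += sq(logy[i] - std::log(mp));
          }
          ok = ok && R_finite(ssr_p);
        }
        if (!ok) continue;
        double lr = -0.5 * tau_nu * (sq(np) - sq(nu[j]));
        if (use_likelihood) lr += -0.5 * tau_y * (ssr_p - ssr);
        if (std::log(R::unif_rand()) < lr) {
          nu[j] = np;
          beta[j] = bp;
          if (use_likelihood) {
            for (int i = 0; i < n; ++i) mu[i] = Wprop[i];
            ssr = ssr_p;
          }
          acc[blk]++;
        }
      }
    }

    // -- ridge move: shift log(theta) against all nu_j --------------------
    // beta_j = theta S_j e^{nu_j} is invariant under (log theta + delta,
    // nu - delta), so the likelihood drops out and the move explores the
    // weakly identified ridge at prior cost only
    if (update_nu) {
      const int blk = G;  // reuses the slot freed by the Gibbs theta draw
      att[blk]++;
      const double delta = std::exp(lsc[blk]) * R::norm_rand();
      const double lt = std::log(theta);
      double lr = R::dnorm(lt + delta, th_m, th_s, 1) -
                  R::dnorm(lt, th_m, th_s, 1);
      for (int j = 0; j < m; ++j)
        lr += -0.5 * tau_nu * (sq(nu[j] - delta) - sq(nu[j]));
      if (std::log(R::unif_rand()) < lr) {
        theta = std::exp(lt + delta);
        for (int j = 0; j < m; ++j) nu[j] -= delta;
        acc[blk]++;
      }
    }

    // -- precisions (conjugate) -------------------------------------------
    if (use_likelihood)
      tau_y = R::rgamma(a_ty + 0.5 * n, 1.0 / (b_ty + 0.5 * ssr));
    else
      tau_y = R::rgamma(a_ty, 1.0 / b_ty);
    if (update_nu) {
      double ssn = 0.0;
      for (int j = 0; j < m; ++j) ssn += sq(nu[j]);
      tau_nu = R::rgamma(a_tn + 0.5 * m, 1.0 / (b_tn + 0.5 * ssn));
    }

    // -- adaptation (burn-in only) ----------------------------------------
    if (it <= n_burn && it % 50 == 0) {
      batch++;
      const double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      for (int b = 0; b < nblk; ++b) {
        if (att[b] > 0) {
          const double rate = (double)acc[b] / att[b];
          lsc[b] += (rate > 0.44 ? delta : -delta);
        }
        acc[b] = 0;
        att[b] = 0;
      }
    }

    // -- storage -----------------------------------------------------------
    if (it > n_burn && (it - n_burn) % thin == 0 && row < n_keep) {
      int c = 0;
      for (int g = 0; g < G; ++g) draws(row, c++) = alpha[g];
      draws(row, c++) = theta;
      for (int j = 0; j < m; ++j) draws(row, c++) = nu[j];
      draws(row, c++) = tau_y;
      draws(row, c++) = tau_nu;
      dev[row] = -n * std::log(tau_y / (2.0 * M_PI)) + tau_y * ssr; // -2*loglik
      row++;
    }
  }

  return List::create(_["draws"] = draws, _["deviance"] = dev,
                      _["n_groups"] = G);
}

// Posterior draws of the mean-turbidity field: one row per retained draw.
// Used by model-selection statistics and recovery scoring; kept in C++ so
// reports stay recomputable from stored chains at negligible cost.
// [[Rcpp::export]]
NumericMatrix mu_from_draws(NumericMatrix draws, NumericMatrix K,
                            NumericVector S, IntegerVector agroup, int G,
                            int stride) {
  const int m = S.size(), n = K.nrow();
  const int nd = draws.nrow();
  std::vector<int> rows;
  for (int r = 0; r < nd; r += stride) rows.push_back(r);
  NumericMatrix out(rows.size(), n);
  for (size_t q = 0; q < rows.size(); ++q) {
    const int r = rows[q];
    const double theta = draws(r, G);
    for (int i = 0; i < n; ++i) out(q, i) = 0.0;
    for (int j = 0; j < m; ++j) {
      const double a = draws(r, agroup[j] - 1);
      const double b = theta * S[j] * std::exp(draws(r, G + 1 + j));
      for (int i = 0; i < n; ++i) out(q, i) += b * std::exp(-a * K(i, j));
    }
  }
  return out;
}
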