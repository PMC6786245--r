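#include <Rcpp.h>
using namespace Rcpp;

// Beta-binomial log-likelihood kernel for one locus x population cell,
// dropping the data-only lchoose(n, a) constant (it cancels from every
// Metropolis-Hastings ratio). A = theta * p, B = theta * (1 - p) with
// theta = (1 - F_ST) / F_ST = exp(-(alpha + beta)).
static inline double bb_kernel(int a, int n, double A, double B) {
  return lgamma(A + B) - lgamma(A + B + n) + lgamma(A + a) - lgamma(A) +
         lgamma(B + n - a) - lgamma(B);
}

static inline double cell_ll(int a, int n, double p, double alpha,
                             double beta) {
  const double theta = std::exp(-(alpha + beta));
  return bb_kernel(a, n, theta * p, theta * (1.0 - p));
}

// Reversible-jump MCMC for the logit-F_ST decomposition
//   F_ST_ij = logistic(delta_i * alpha_i + beta_j)
// with priors alpha ~ N(0, alpha_sd), beta ~ N(beta_mean, beta_sd),
// p_i ~ Uniform(0,1) (logit random walk, kept interior), and
// P(delta_i = 1) = prior_incl. Uses R's RNG, so set.seed() in R makes runs
// reproducible. `likelihood_on = false` switches the likelihood off (all
// cells contribute 0), a hook for prior-recovery checks.
// [[Rcpp::export]]
List cpp_rjmcmc(const IntegerMatrix& a, const IntegerMatrix& n,
                int burn_in, int n_iter, int thin, double prior_incl,
                double alpha_sd, double beta_mean, double beta_sd,
                double prop_p, double prop_alpha, double prop_beta,
                bool likelihood_on, bool adapt) {
  const int I = a.nrow(), J = a.ncol();
  const double log_odds_incl =
      std::log(prior_incl) - std::log(1.0 - prior_incl);

  std::vector<double> p(I), alpha(I, 0.0), beta(J, beta_mean);
  std::vector<int> delta(I, 0);
  for (int i = 0; i < I; ++i) {
    double num = 1.0, den = 2.0;
    for (int j = 0; j < J; ++j) { num += a(i, j); den += n(i, j); }
    p[i] = num / den;
  }

  // current log-likelihood per cell
  NumericMatrix ll(I, J);
  auto row_ll = [&](int i, double pi, double al) {
    double s = 0.0;
    if (!likelihood_on) return 0.0;
    for (int j = 0; j < J; ++j) s += cell_ll(a(i, j), n(i, j), pi, al, beta[j]);
    return s;
  };
  if (likelihood_on)
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j)
        ll(i, j) = cell_ll(a(i, j), n(i, j), p[i],
                           delta[i] ? alpha[i] : 0.0, beta[j]);

  auto set_row = [&](int i, double pi, double al) {
    if (!likelihood_on) return;
    for (int j = 0; j < J; ++j)
      ll(i, j) = cell_ll(a(i, j), n(i, j), pi, al, beta[j]);
  };
  auto row_sum = [&](int i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += ll(i, j);
    return s;
  };

  const int S = n_iter / thin;
  IntegerMatrix out_delta(S, I);
  NumericMatrix out_alpha(S, I), out_beta(S, J);
  std::vector<double> p_sum(I, 0.0);
  long acc_p = 0, try_p = 0, acc_a = 0, try_a = 0, acc_b = 0, try_b = 0,
       acc_rj = 0, try_rj = 0;
  long w_acc_p = 0, w_try_p = 0, w_acc_a = 0, w_try_a = 0, w_acc_b = 0,
       w_try_b = 0;

  RNGScope scope;
  int stored = 0;
  const int total = burn_in + n_iter;
  for (int it = 0; it < total; ++it) {
    const bool in_burn = it < burn_in;

    // --- ancestral frequencies: logit random walk, uniform prior ---
    for (int i = 0; i < I; ++i) {
      const double x = std::log(p[i] / (1.0 - p[i]));
      const double xn = x + R::norm_rand() * prop_p;
      const double pn = 1.0 / (1.0 + std::exp(-xn));
      if (pn <= 0.0 || pn >= 1.0) { ++try_p; ++w_try_p; continue; }
      const double al = delta[i] ? alpha[i] : 0.0;
      const double cur = row_sum(i);
      const double prop = row_ll(i, pn, al);
      const double jac = std::log(pn * (1.0 - pn)) -
                         std::log(p[i] * (1.0 - p[i]));
      ++try_p; ++w_try_p;
      if (std::log(R::unif_rand()) < prop - cur + jac) {
        p[i] = pn;
        set_row(i, pn, al);
        ++acc_p; ++w_acc_p;
      }
    }

    // --- population effects beta_j ---
    for (int j = 0; j < J; ++j) {
      const double bn = beta[j] + R::norm_rand() * prop_beta;
      double dll = 0.0;
      std::vector<double> newcol;
      if (likelihood_on) {
        newcol.resize(I);
        const double old_beta = beta[j];
        for (int i = 0; i < I; ++i) {
          const double al = delta[i] ? alpha[i] : 0.0;
          const double theta = std::exp(-(al + bn));
          newcol[i] = bb_kernel(a(i, j), n(i, j), theta * p[i],
                                theta * (1.0 - p[i]));
          dll += newcol[i] - ll(i, j);
        }
        (void)old_beta;
      }
      const double dprior =
          R::dnorm(bn, beta_mean, beta_sd, 1) -
          R::dnorm(beta[j], beta_mean, beta_sd, 1);
      ++try_b; ++w_try_b;
      if (std::log(R::unif_rand()) < dll + dprior) {
        beta[j] = bn;
        if (likelihood_on)
          for (int i = 0; i < I; ++i) ll(i, j) = newcol[i];
        ++acc_b; ++w_acc_b;
      }
    }

    // --- locus effects alpha_i (only included loci) ---
    for (int i = 0; i < I; ++i) {
      if (!delta[i]) continue;
      const double an = alpha[i] + R::norm_rand() * prop_alpha;
      const double cur = row_sum(i);
      const double prop = row_ll(i, p[i], an);
      const double dprior = R::dnorm(an, 0.0, alpha_sd, 1) -
                            R::dnorm(alpha[i], 0.0, alpha_sd, 1);
      ++try_a; ++w_try_a;
      if (std::log(R::unif_rand()) < prop - cur + dprior) {
        alpha[i] = an;
        set_row(i, p[i], an);
        ++acc_a; ++w_acc_a;
      }
    }

    // --- reversible-jump toggles: alpha proposed from its prior, so the
    // prior density cancels the proposal and the ratio is likelihood times
    // prior inclusion odds ---
    for (int i = 0; i < I; ++i) {
      ++try_rj;
      const double cur = row_sum(i);
      if (!delta[i]) {
        const double an = R::norm_rand() * alpha_sd;
        const double prop = row_ll(i, p[i], an);
        if (std::log(R::unif_rand()) < prop - cur + log_odds_incl) {
          delta[i] = 1;
          alpha[i] = an;
          set_row(i, p[i], an);
          ++acc_rj;
        }
      } else {
        const double prop = row_ll(i, p[i], 0.0);
        if (std::log(R::unif_rand()) < prop - cur - log_odds_incl) {
          delta[i] = 0;
          alpha[i] = 0.0;
          set_row(i, p[i], 0.0);
          ++acc_rj;
        }
      }
    }

    // --- proposal adaptation during burn-in, frozen afterwards ---
    if (adapt && in_burn && (it + 1) % 100 == 0) {
      auto tune = [](double sd, long acc, long tries) {
        if (tries == 0) return sd;
        const double r = (double)acc / tries;
        if (r > 0.45) return sd * 1.3;
        if (r < 0.25) return sd / 1.3;
        return sd;
      };
      prop_p = tune(prop_p, w_acc_p, w_try_p);
      prop_alpha = tune(prop_alpha, w_acc_a, w_try_a);
      prop_beta = tune(prop_beta, w_acc_b, w_try_b);
      w_acc_p = w_try_p = w_acc_a = w_try_a = w_acc_b = w_try_b = 0;
    }

    if (!in_burn && (it - burn_in + 1) % thin == 0) {
      for (int i = 0; i < I; ++i) {
        out_delta(stored, i) = delta[i];
        out_alpha(stored, i) = delta[i] ? alpha[i] : 0.0;
        p_sum[i] += p[i];
      }
      for (int j = 0; j < J; ++j) out_beta(stored, j) = beta[j];
      ++stored;
    }
  }

  NumericVector p_mean(I);
  for (int i = 0; i < I; ++i) p_mean[i] = p_sum[i] / std::max(stored, 1);
  return List::create(
      _["delta"] = out_delta, _["alpha"] = out_alpha, _["beta"] = out_beta,
      _["p_mean"] = p_mean,
      _["accept"] = NumericVector::create(
          _["p"] = try_p ? (double)acc_p / try_p : NA_REAL,
          _["alpha"] = try_a ? (double)acc_a / try_a : NA_REAL,
          _["beta"] = try_b ? (double)acc_b / try_b : NA_REAL,
          _["rj"] = try_rj ? (double)acc_rj / try_rj : NA_REAL),
      _["prop_sds"] = NumericVector::create(_["p"] = prop_p,
                                            _["alpha"] = prop_alpha,
                                            _["beta"] = prop_beta));
}
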