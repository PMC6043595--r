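#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log-likelihood with logit link, numerically stable.
static inline double bern_loglik(const NumericVector& eta,
                                 const IntegerVector& y) {
  const int n = eta.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double e = eta[i];
    const double lse = (e > 30.0) ? e : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

// Adaptive Metropolis-within-Gibbs for the monotone penalized B-spline
// Bernoulli model, one chain.
//
// Parameterization: alpha_k = alpha_1 + sum_{j<=k} delta_j. Because the
// basis rows sum to one, eta = alpha_1 + Cd %*% delta with
// Cd[i, j] = sum_{k >= j+1} B[i, k] (reversed row cumsums, columns 2..K).
//
// Priors: alpha_1 ~ N(0, alpha1_prior_sd^2); delta_j ~ N(0, sigma^2),
// truncated to delta_j >= 0 when monotone; sigma ~ half-Cauchy(scale).
// The half-Cauchy is handled by its inverse-gamma scale-mixture
// (sigma^2 | aux ~ IG(1/2, 1/aux), aux ~ IG(1/2, 1/scale^2)), which gives
// conjugate Gibbs draws for sigma^2 and aux.
//
// Moves per sweep: RW on alpha_1; RW on each delta_j (proposals below zero
// rejected when monotone); a "seesaw" joint move (alpha_1 += e,
// delta_j -= e for one random j) that tracks the posterior ridge between
// the curve's left boundary value and the increments; Gibbs for sigma.
// Step sizes adapt toward 0.44 acceptance during burn-in only.
// [[Rcpp::export]]
List mcmc_pspline_chain(NumericMatrix Cd, IntegerVector y,
                        int n_iter, int burn, int thin, bool monotone,
                        double alpha1_prior_sd, double sigma_cauchy_scale,
                        NumericVector init) {
  const int n = y.size();
  const int nd = Cd.ncol();        // K - 1 increments
  const int nstep = nd + 2;        // alpha1, deltas, seesaw

  double alpha1 = init[0];
  std::vector<double> delta(nd);
  for (int j = 0; j < nd; ++j) delta[j] = init[1 + j];
  double sig2 = std::exp(2.0 * init[nd + 1]);
  double aux = 1.0;

  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = alpha1;
    for (int j = 0; j < nd; ++j) e += Cd(i, j) * delta[j];
    eta[i] = e;
  }
  double ll = bern_loglik(eta, y);
  double sumsq = 0.0;
  for (int j = 0; j < nd; ++j) sumsq += delta[j] * delta[j];

  std::vector<double> lstep(nstep, -1.0);  // log proposal sd, adapted
  std::vector<int> acc(nstep, 0), tries(nstep, 0);
  std::vector<int> acc_batch(nstep, 0), try_batch(nstep, 0);
  const int batch_len = 50;
  const double target = 0.44;
  const double a1v = alpha1_prior_sd * alpha1_prior_sd;
  const double c2 = sigma_cauchy_scale * sigma_cauchy_scale;

  const int n_keep = (n_iter - burn) / thin;
  NumericMatrix draws(n_keep, nd + 2);
  int keep_row = 0;

  NumericVector eta_prop(n);

  for (int it = 0; it < n_iter; ++it) {
    // --- alpha_1, random walk ---
    {
      const double step = std::exp(lstep[0]);
      const double prop = alpha1 + step * R::norm_rand();
      const double shift = prop - alpha1;
      for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + shift;
      const double ll_new = bern_loglik(eta_prop, y);
      const double dprior = -0.5 * (prop * prop - alpha1 * alpha1) / a1v;
      tries[0]++; try_batch[0]++;
      if (std::log(R::unif_rand()) < ll_new - ll + dprior) {
        alpha1 = prop; ll = ll_new;
        std::copy(eta_prop.begin(), eta_prop.end(), eta.begin());
        acc[0]++; acc_batch[0]++;
      }
    }
    // --- increments delta_j, random walk ---
    for (int j = 0; j < nd; ++j) {
      const int p = 1 + j;
      const double step = std::exp(lstep[p]);
      const double old = delta[j];
      const double prop = old + step * R::norm_rand();
      tries[p]++; try_batch[p]++;
      if (monotone && prop < 0.0) continue;   // zero prior mass
      const double d = prop - old;
      for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + Cd(i, j) * d;
      const double ll_new = bern_loglik(eta_prop, y);
      const double dprior = -0.5 * (prop * prop - old * old) / sig2;
      if (std::log(R::unif_rand()) < ll_new - ll + dprior) {
        delta[j] = prop; ll = ll_new;
        sumsq += prop * prop - old * old;
        std::copy(eta_prop.begin(), eta_prop.end(), eta.begin());
        acc[p]++; acc_batch[p]++;
      }
    }
    // --- seesaw: alpha_1 += e, delta_j -= e for one random j ---
    {
      const int p = nstep - 1;
      const int j = (int)std::floor(R::unif_rand() * nd);
      const double step = std::exp(lstep[p]);
      const double e = step * R::norm_rand();
      const double a_prop = alpha1 + e;
      const double d_prop = delta[j] - e;
      tries[p]++; try_batch[p]++;
      if (!(monotone && d_prop < 0.0)) {
        for (int i = 0; i < n; ++i)
          eta_prop[i] = eta[i] + e * (1.0 - Cd(i, j));
        const double ll_new = bern_loglik(eta_prop, y);
        const double dprior =
          -0.5 * (a_prop * a_prop - alpha1 * alpha1) / a1v
          - 0.5 * (d_prop * d_prop - delta[j] * delta[j]) / sig2;
        if (std::log(R::unif_rand()) < ll_new - ll + dprior) {
          alpha1 = a_prop;
          sumsq += d_prop * d_prop - delta[j] * delta[j];
          delta[j] = d_prop; ll = ll_new;
          std::copy(eta_prop.begin(), eta_prop.end(), eta.begin());
          acc[p]++; acc_batch[p]++;
        }
      }
    }
    // --- sigma^2 and mixture auxiliary, conjugate Gibbs ---
    {
      const double rate_s = 1.0 / aux + 0.5 * sumsq;
      sig2 = 1.0 / R::rgamma(0.5 * (nd + 1), 1.0 / rate_s);
      const double rate_a = 1.0 / c2 + 1.0 / sig2;
      aux = 1.0 / R::rgamma(1.0, 1.0 / rate_a);
    }
    // --- batch adaptation, burn-in only ---
    if (it < burn && (it + 1) % batch_len == 0) {
      const double adapt = std::min(0.1, 5.0 / std::sqrt((double)(it + 1)));
      for (int p = 0; p < nstep; ++p) {
        const double rate = try_batch[p] > 0 ?
          (double)acc_batch[p] / try_batch[p] : 0.0;
        lstep[p] += (rate > target) ? adapt : -adapt;
        acc_batch[p] = 0; try_batch[p] = 0;
      }
    }
    if (it >= burn && (it - burn) % thin == 0 && keep_row < n_keep) {
      draws(keep_row, 0) = alpha1;
      for (int j = 0; j < nd; ++j) draws(keep_row, 1 + j) = delta[j];
      draws(keep_row, nd + 1) = std::sqrt(sig2);
      keep_row++;
    }
  }

  NumericVector acc_rate(nstep);
  for (int p = 0; p < nstep; ++p)
    acc_rate[p] = tries[p] > 0 ? (double)acc[p] / tries[p] : NA_REAL;
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate);
}
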