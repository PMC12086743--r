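// Core numerics for the nested Rescorla-Wagner Go/No-Go family:
// per-subject sequence log-likelihood, a generative agent, and one chain of
// the hierarchical adaptive Metropolis-within-Gibbs sampler.
#include <Rcpp.h>
using namespace Rcpp;

// canonical natural parameter layout: xi, ep, b, pi, rhoRew, rhoPun
static const int N_STIM = 4;

// number of free (sampled) parameters per model
static int n_free(int model) { return model + 2; }

// expand a free z-vector (sampling scale) into canonical natural parameters.
// free ordering: m1 [xi, ep, rho]; m2 [xi, ep, b, rho];
// m3 [xi, ep, b, pi, rho]; m4 [xi, ep, b, pi, rhoRew, rhoPun]
static void z_to_nat(const double* z, int model, double* nat) {
  nat[0] = R::pnorm(z[0], 0.0, 1.0, 1, 0); // xi
  nat[1] = R::pnorm(z[1], 0.0, 1.0, 1, 0); // ep
  int k = 2;
  nat[2] = (model >= 2) ? z[k++] : 0.0;    // b
  nat[3] = (model >= 3) ? z[k++] : 0.0;    // pi
  double rR = std::exp(z[k++]);
  nat[4] = rR;
  nat[5] = (model == 4) ? std::exp(z[k]) : rR;
}

// forward-pass log-likelihood of one subject's sequence; optionally fills
// the pointwise vector
static double subj_ll(const int* stim, const int* go, const int* outc, int T,
                      const double* nat, double* pw) {
  double qgo[N_STIM] = {0, 0, 0, 0};
  double qng[N_STIM] = {0, 0, 0, 0};
  double v[N_STIM]  = {0, 0, 0, 0};
  const double xi = nat[0], ep = nat[1], b = nat[2], pi = nat[3],
               rR = nat[4], rP = nat[5];
  double ll = 0.0;
  for (int t = 0; t < T; t++) {
    const int s = stim[t] - 1;
    const double wdiff = qgo[s] + b + pi * v[s] - qng[s];
    const double p = (1.0 - xi) / (1.0 + std::exp(-wdiff)) + 0.5 * xi;
    const double lp = go[t] ? std::log(p) : std::log1p(-p);
    if (pw) pw[t] = lp;
    ll += lp;
    const double r = (double) outc[t];
    const double target = (r >= 0.0 ? rR : rP) * r;
    v[s] += ep * (target - v[s]);
    if (go[t]) qgo[s] += ep * (target - qgo[s]);
    else       qng[s] += ep * (target - qng[s]);
  }
  return ll;
}

// [[Rcpp::export]]
List gng_seq_loglik(IntegerVector stim, IntegerVector chosen_go,
                    IntegerVector outcome, NumericVector nat) {
  const int T = stim.size();
  if (chosen_go.size() != T || outcome.size() != T)
    stop("stim, chosen_go, outcome must have equal length");
  for (int t = 0; t < T; t++) {
    if (stim[t] < 1 || stim[t] > N_STIM) stop("stimulus index out of range");
    if (outcome[t] < -1 || outcome[t] > 1) stop("outcome must be -1, 0 or +1");
  }
  NumericVector pw(T);
  double total = subj_ll(stim.begin(), chosen_go.begin(), outcome.begin(),
                         T, nat.begin(), pw.begin());
  return List::create(_["total"] = total, _["pointwise"] = pw);
}

// [[Rcpp::export]]
List gng_simulate_agent(IntegerVector stim, IntegerVector required_go,
                        IntegerVector is_win, NumericVector nat,
                        NumericVector u_choice, NumericVector u_cong,
                        double congruence_prob) {
  const int T = stim.size();
  IntegerVector chosen(T), outcome(T);
  double qgo[N_STIM] = {0, 0, 0, 0};
  double qng[N_STIM] = {0, 0, 0, 0};
  double v[N_STIM]  = {0, 0, 0, 0};
  const double xi = nat[0], ep = nat[1], b = nat[2], pi = nat[3],
               rR = nat[4], rP = nat[5];
  for (int t = 0; t < T; t++) {
    const int s = stim[t] - 1;
    const double wdiff = qgo[s] + b + pi * v[s] - qng[s];
    const double p = (1.0 - xi) / (1.0 + std::exp(-wdiff)) + 0.5 * xi;
    const int go = u_choice[t] < p ? 1 : 0;
    chosen[t] = go;
    const bool correct = (go == required_go[t]);
    // congruent-outcome rule (matches deliver_outcome)
    const bool congruent = u_cong[t] < congruence_prob;
    int expected = is_win[t] ? (correct ? 1 : 0) : (correct ? 0 : -1);
    int other    = is_win[t] ? 1 - expected      : -1 - expected;
    const int r = congruent ? expected : other;
    outcome[t] = r;
    const double target = (r >= 0 ? rR : rP) * (double) r;
    v[s] += ep * (target - v[s]);
    if (go) qgo[s] += ep * (target - qgo[s]);
    else    qng[s] += ep * (target - qng[s]);
  }
  return List::create(_["chosen_go"] = chosen, _["outcome"] = outcome);
}

static double half_normal_lp(double x, double scale) {
  return -0.5 * (x * x) / (scale * scale); // up to a constant, x >= 0
}

// One chain of the hierarchical sampler. Subjects share a group normal per
// free parameter on the sampling scale: z_ip ~ N(mu_p, sigma_p), with
// mu_p ~ N(loc, scale) (conjugate Gibbs) and sigma_p ~ half-N(sd_scale)
// (exact conditional independence proposal). Subject-level z are updated
// one parameter at a time by adaptive random-walk Metropolis against the
// sequence log-likelihood; interweaved rescaling and translation moves of
// (sigma_p, z_.p) and (mu_p, z_.p) remove the funnel coupling. RNG is R's
// stream, so R-side set.seed() governs the chain.
// [[Rcpp::export]]
List gng_mcmc_chain(IntegerVector stim, IntegerVector chosen_go,
                    IntegerVector outcome,
                    IntegerVector subj_start, IntegerVector subj_len,
                    int model, int n_warmup, int n_keep, int thin,
                    NumericVector mu_loc, NumericVector mu_scale,
                    NumericVector sd_scale, bool store_loglik) {
  const int N = subj_start.size();
  const int P = n_free(model);
  const int Ttot = stim.size();
  if (mu_loc.size() != P || mu_scale.size() != P || sd_scale.size() != P)
    stop("prior vectors must have length %d for model m%d", P, model);

  std::vector<double> mu(P, 0.0), sigma(P, 0.15);
  std::vector<double> z(N * P), ll(N), nat(6);
  std::vector<double> step_z(P, 0.25), step_nc(P, 0.15), step_tr(P, 0.15);
  std::vector<double> z_prop(N), ll_prop(N);

  const int* stim_p = stim.begin();
  const int* go_p = chosen_go.begin();
  const int* out_p = outcome.begin();

  // initialize with bounded retries until all subject likelihoods are finite
  bool ok = false;
  for (int attempt = 0; attempt < 20 && !ok; attempt++) {
    for (int i = 0; i < N; i++)
      for (int p = 0; p < P; p++)
        z[i * P + p] = mu[p] + 0.3 * R::norm_rand();
    ok = true;
    for (int i = 0; i < N; i++) {
      z_to_nat(&z[i * P], model, nat.data());
      ll[i] = subj_ll(stim_p + subj_start[i], go_p + subj_start[i],
                      out_p + subj_start[i], subj_len[i], nat.data(), NULL);
      if (!R_finite(ll[i])) { ok = false; break; }
    }
  }
  if (!ok) stop("non-finite likelihood at initialization after 20 retries");

  const int n_iter = n_warmup + n_keep * thin;
  NumericMatrix out_mu(n_keep, P), out_sigma(n_keep, P);
  NumericMatrix out_theta(n_keep, N * P);
  NumericMatrix out_ll(store_loglik ? n_keep : 1,
                       store_loglik ? Ttot : 1);
  std::vector<double> pw(Ttot);
  int kept = 0;

  for (int it = 0; it < n_iter; it++) {
    const double gamma = 0.5 / std::pow(it + 1.0, 0.6);
    // group means: conjugate Gibbs
    for (int p = 0; p < P; p++) {
      double s2 = sigma[p] * sigma[p];
      double zsum = 0.0;
      for (int i = 0; i < N; i++) zsum += z[i * P + p];
      double prec = N / s2 + 1.0 / (mu_scale[p] * mu_scale[p]);
      double mean = (zsum / s2 + mu_loc[p] / (mu_scale[p] * mu_scale[p])) / prec;
      mu[p] = mean + R::norm_rand() / std::sqrt(prec);
    }
    // group sds: independence proposal from the conditional that the
    // z-deviations imply (inverse-gamma in sigma^2, which cancels the
    // likelihood and Jacobian exactly), MH-corrected by the half-normal
    // prior ratio alone
    for (int p = 0; p < P; p++) {
      double d2 = 0.0;
      for (int i = 0; i < N; i++) {
        double d = z[i * P + p] - mu[p];
        d2 += d * d;
      }
      double u_old = sigma[p] * sigma[p];
      double u_new = (0.5 * d2) / R::rgamma(0.5 * (N - 1), 1.0);
      double la = (u_old - u_new) / (2.0 * sd_scale[p] * sd_scale[p]);
      if (std::log(R::unif_rand()) < la) sigma[p] = std::sqrt(u_new);
    }
    // subject-level z: per-parameter adaptive RWM
    for (int p = 0; p < P; p++) {
      double acc_sum = 0.0;
      for (int i = 0; i < N; i++) {
        double* zi = &z[i * P];
        double z_old = zi[p];
        double z_new = z_old + step_z[p] * R::norm_rand();
        zi[p] = z_new;
        z_to_nat(zi, model, nat.data());
        double ll_new = subj_ll(stim_p + subj_start[i], go_p + subj_start[i],
                                out_p + subj_start[i], subj_len[i],
                                nat.data(), NULL);
        double la = ll_new - ll[i]
          + R::dnorm(z_new, mu[p], sigma[p], 1)
          - R::dnorm(z_old, mu[p], sigma[p], 1);
        double acc = (R_finite(la) && la > 0) ? 1.0
                     : (R_finite(la) ? std::exp(la) : 0.0);
        acc_sum += acc;
        if (R_finite(la) && std::log(R::unif_rand()) < la) {
          ll[i] = ll_new;
        } else {
          zi[p] = z_old;
        }
      }
      if (it < n_warmup)
        step_z[p] *= std::exp(gamma * (acc_sum / N - 0.44));
    }
    // interweaving (ancillary) move: with the standardized subject effects
    // eta_i = (z_ip - mu_p)/sigma_p held fixed, rescale sigma_p and all
    // subject deviations together. Breaks the funnel coupling between the
    // group spread and the subject-level effects.
    for (int p = 0; p < P; p++) {
      double ls = std::log(sigma[p]);
      double ls_new = ls + step_nc[p] * R::norm_rand();
      double s_new = std::exp(ls_new);
      double lp = half_normal_lp(s_new, sd_scale[p])
                - half_normal_lp(sigma[p], sd_scale[p])
                + ls_new - ls;
      bool finite = true;
      for (int i = 0; i < N; i++) {
        double eta = (z[i * P + p] - mu[p]) / sigma[p];
        z_prop[i] = mu[p] + s_new * eta;
        double z_old = z[i * P + p];
        z[i * P + p] = z_prop[i];
        z_to_nat(&z[i * P], model, nat.data());
        ll_prop[i] = subj_ll(stim_p + subj_start[i], go_p + subj_start[i],
                             out_p + subj_start[i], subj_len[i],
                             nat.data(), NULL);
        z[i * P + p] = z_old;
        if (!R_finite(ll_prop[i])) { finite = false; break; }
        lp += ll_prop[i] - ll[i];
      }
      double acc = (finite && R_finite(lp))
                   ? (lp > 0 ? 1.0 : std::exp(lp)) : 0.0;
      if (finite && R_finite(lp) && std::log(R::unif_rand()) < lp) {
        sigma[p] = s_new;
        for (int i = 0; i < N; i++) {
          z[i * P + p] = z_prop[i];
          ll[i] = ll_prop[i];
        }
      }
      if (it < n_warmup)
        step_nc[p] *= std::exp(gamma * (acc - 0.44));
    }
    // companion translation move: shift mu_p and all subject z together
    // (deviations fixed), so the group mean can traverse even when the
    // subject-level values are data-pinned
    for (int p = 0; p < P; p++) {
      double mu_new = mu[p] + step_tr[p] * R::norm_rand();
      double shift = mu_new - mu[p];
      double lp = R::dnorm(mu_new, mu_loc[p], mu_scale[p], 1)
                - R::dnorm(mu[p], mu_loc[p], mu_scale[p], 1);
      bool finite = true;
      for (int i = 0; i < N; i++) {
        z_prop[i] = z[i * P + p] + shift;
        double z_old = z[i * P + p];
        z[i * P + p] = z_prop[i];
        z_to_nat(&z[i * P], model, nat.data());
        ll_prop[i] = subj_ll(stim_p + subj_start[i], go_p + subj_start[i],
                             out_p + subj_start[i], subj_len[i],
                             nat.data(), NULL);
        z[i * P + p] = z_old;
        if (!R_finite(ll_prop[i])) { finite = false; break; }
        lp += ll_prop[i] - ll[i];
      }
      double acc = (finite && R_finite(lp))
                   ? (lp > 0 ? 1.0 : std::exp(lp)) : 0.0;
      if (finite && R_finite(lp) && std::log(R::unif_rand()) < lp) {
        mu[p] = mu_new;
        for (int i = 0; i < N; i++) {
          z[i * P + p] = z_prop[i];
          ll[i] = ll_prop[i];
        }
      }
      if (it < n_warmup)
        step_tr[p] *= std::exp(gamma * (acc - 0.44));
    }
    // store
    if (it >= n_warmup && ((it - n_warmup + 1) % thin == 0)) {
      for (int p = 0; p < P; p++) {
        out_mu(kept, p) = mu[p];
        out_sigma(kept, p) = sigma[p];
      }
      for (int i = 0; i < N; i++) {
        z_to_nat(&z[i * P], model, nat.data());
        // store natural-scale free parameters, in free ordering
        int k = 0;
        out_theta(kept, i * P + k++) = nat[0];          // xi
        out_theta(kept, i * P + k++) = nat[1];          // ep
        if (model >= 2) out_theta(kept, i * P + k++) = nat[2]; // b
        if (model >= 3) out_theta(kept, i * P + k++) = nat[3]; // pi
        out_theta(kept, i * P + k++) = nat[4];          // rho / rhoRew
        if (model == 4) out_theta(kept, i * P + k++) = nat[5]; // rhoPun
        if (store_loglik) {
          subj_ll(stim_p + subj_start[i], go_p + subj_start[i],
                  out_p + subj_start[i], subj_len[i], nat.data(),
                  pw.data() + subj_start[i]);
        }
      }
      if (store_loglik)
        for (int t = 0; t < Ttot; t++) out_ll(kept, t) = pw[t];
      kept++;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mu"] = out_mu, _["sigma"] = out_sigma,
                      _["theta"] = out_theta,
                      _["log_lik"] = out_ll,
                      _["step_z"] = NumericVector(step_z.begin(), step_z.end()));
}
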