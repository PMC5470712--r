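#include <Rcpp.h>
using namespace Rcpp;

// Conditional-logit choice-set samplers.  Design matrix X is (3n x P)
// with the three rows of set i at 3i..3i+2 (0-based); used[i] in {0,1,2}.
// Utilities V = X beta are cached and updated incrementally per
// coordinate proposal, as are the per-set log-likelihood contributions;
// log-likelihoods always go through the max-shifted log-sum-exp.

static inline double set_ll(const double* v, int used) {
  double m = v[0];
  if (v[1] > m) m = v[1];
  if (v[2] > m) m = v[2];
  return v[used] - m - std::log(std::exp(v[0] - m) + std::exp(v[1] - m) +
                                std::exp(v[2] - m));
}

// Random-walk Metropolis for the pooled (nest) model: one shared beta,
// independent N(prior_mean, 1/prior_prec) priors on each coordinate.
// Per-coordinate proposal scales adapt toward a 0.23-0.44 acceptance
// rate during burn-in only.  Uses the R RNG (seed via set.seed()).
// [[Rcpp::export(name = ".sampler_pooled")]]
List sampler_pooled(const NumericMatrix& X, const IntegerVector& used,
                    int n_iter, int n_burnin, int thin,
                    double prior_mean, double prior_prec,
                    NumericVector init_beta, double init_scale,
                    int adapt_interval) {
  const int n = used.size(), P = X.ncol(), nr = X.nrow();
  if (nr != 3 * n) stop("X must have 3 rows per choice set");
  const double* xp = &X[0];  // column-major: xp[k * nr + r]
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector<double> V(3 * n, 0.0), cur(n), prop(n), Vp(3);
  for (int r = 0; r < nr; ++r) {
    double s = 0.0;
    for (int k = 0; k < P; ++k) s += xp[k * nr + r] * beta[k];
    V[r] = s;
  }
  for (int i = 0; i < n; ++i) cur[i] = set_ll(&V[3 * i], used[i]);
  std::vector<double> scale(P, init_scale);
  std::vector<int> acc(P, 0), tries(P, 0);

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix out(n_keep, P);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int k = 0; k < P; ++k) {
      const double* xk = xp + (size_t)k * nr;
      double d = R::norm_rand() * scale[k];
      double bnew = beta[k] + d;
      double dll = -0.5 * prior_prec *
        ((bnew - prior_mean) * (bnew - prior_mean) -
         (beta[k] - prior_mean) * (beta[k] - prior_mean));
      for (int i = 0; i < n; ++i) {
        Vp[0] = V[3 * i]     + d * xk[3 * i];
        Vp[1] = V[3 * i + 1] + d * xk[3 * i + 1];
        Vp[2] = V[3 * i + 2] + d * xk[3 * i + 2];
        prop[i] = set_ll(&Vp[0], used[i]);
        dll += prop[i] - cur[i];
      }
      ++tries[k];
      if (std::log(R::unif_rand()) < dll) {
        beta[k] = bnew;
        for (int r = 0; r < nr; ++r) V[r] += d * xk[r];
        cur.swap(prop);
        ++acc[k];
      }
    }
    if (it <= n_burnin && it % adapt_interval == 0) {
      for (int k = 0; k < P; ++k) {
        double rate = tries[k] ? (double)acc[k] / tries[k] : 0.0;
        if (rate > 0.44) scale[k] *= 1.4;
        else if (rate < 0.23) scale[k] /= 1.4;
        acc[k] = tries[k] = 0;
      }
    }
    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      for (int k = 0; k < P; ++k) out(kept, k) = beta[k];
      ++kept;
    }
  }
  return List::create(_["beta"] = out,
                      _["scale"] = NumericVector(scale.begin(), scale.end()));
}

// Hierarchical (postfledging) model.  unit[i] maps set i to its
// individual-stage unit u (0-based), unit_stage[u] to its model stage.
// beta_{u,k} ~ N(mu_{s,k}, 1/tau_{s,k}); mu has N(mu0, prec0) priors,
// tau has Gamma(shape, rate) priors.  beta updated by adaptive RWM on
// the unit's own sets; mu and tau by conjugate Gibbs draws.  Starting
// values (init_mu, init_beta) should be overdispersed across chains;
// in particular the initial unit coefficients must not coincide, or the
// first precision draw would start the chain inside the degenerate
// sigma ~ 0 corner.
// [[Rcpp::export(name = ".sampler_hier")]]
List sampler_hier(const NumericMatrix& X, const IntegerVector& used,
                  const IntegerVector& unit, const IntegerVector& unit_stage,
                  int n_units, int n_stages,
                  int n_iter, int n_burnin, int thin,
                  double mu0, double prec0,
                  double tau_shape, double tau_rate,
                  NumericVector init_mu, NumericVector init_beta,
                  double init_scale, int adapt_interval) {
  const int n = used.size(), P = X.ncol(), nr = X.nrow();
  if (nr != 3 * n) stop("X must have 3 rows per choice set");
  if (init_mu.size() != n_stages * P) stop("init_mu has wrong length");
  if (init_beta.size() != n_units * P) stop("init_beta has wrong length");
  const double* xp = &X[0];

  std::vector<std::vector<int>> usets(n_units);
  for (int i = 0; i < n; ++i) usets[unit[i]].push_back(i);
  std::vector<int> stage_n(n_stages, 0);
  for (int u = 0; u < n_units; ++u) ++stage_n[unit_stage[u]];

  std::vector<double> mu(init_mu.begin(), init_mu.end());
  std::vector<double> tau(n_stages * P, 1.0);
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector<double> V(3 * n, 0.0), cur(n), prop(n), Vp(3);
  for (int i = 0; i < n; ++i) {
    const int u = unit[i];
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      const int r = 3 * i + j;
      for (int k = 0; k < P; ++k) s += xp[k * nr + r] * beta[u * P + k];
      V[r] = s;
    }
    cur[i] = set_ll(&V[3 * i], used[i]);
  }
  std::vector<double> scale(n_units * P, init_scale);
  std::vector<int> acc(n_units * P, 0), tries(n_units * P, 0);
  std::vector<double> tscale(n_stages * P, 0.5);
  std::vector<int> tacc(n_stages * P, 0), ttries(n_stages * P, 0);
  std::vector<double> mscale(n_stages * P, 0.1);
  std::vector<int> macc(n_stages * P, 0), mtries(n_stages * P, 0);

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix out_mu(n_keep, n_stages * P), out_sd(n_keep, n_stages * P),
                out_beta(n_keep, n_units * P);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // individual-level coefficients
    for (int u = 0; u < n_units; ++u) {
      const int s = unit_stage[u];
      const std::vector<int>& sets = usets[u];
      for (int k = 0; k < P; ++k) {
        const int idx = u * P + k;
        const double* xk = xp + (size_t)k * nr;
        double b = beta[idx];
        double d = R::norm_rand() * scale[idx];
        double bnew = b + d;
        double m = mu[s * P + k], t = tau[s * P + k];
        double dll = -0.5 * t * ((bnew - m) * (bnew - m) - (b - m) * (b - m));
        for (size_t j = 0; j < sets.size(); ++j) {
          const int i = sets[j];
          Vp[0] = V[3 * i]     + d * xk[3 * i];
          Vp[1] = V[3 * i + 1] + d * xk[3 * i + 1];
          Vp[2] = V[3 * i + 2] + d * xk[3 * i + 2];
          prop[i] = set_ll(&Vp[0], used[i]);
          dll += prop[i] - cur[i];
        }
        ++tries[idx];
        if (std::log(R::unif_rand()) < dll) {
          beta[idx] = bnew;
          for (size_t j = 0; j < sets.size(); ++j) {
            const int i = sets[j];
            V[3 * i]     += d * xk[3 * i];
            V[3 * i + 1] += d * xk[3 * i + 1];
            V[3 * i + 2] += d * xk[3 * i + 2];
            cur[i] = prop[i];
          }
          ++acc[idx];
        }
      }
    }
    // population means: conjugate normal
    for (int s = 0; s < n_stages; ++s)
      for (int k = 0; k < P; ++k) {
        double sum_b = 0.0;
        for (int u = 0; u < n_units; ++u)
          if (unit_stage[u] == s) sum_b += beta[u * P + k];
        double t = tau[s * P + k];
        double post_prec = t * stage_n[s] + prec0;
        double post_mean = (t * sum_b + prec0 * mu0) / post_prec;
        mu[s * P + k] = post_mean + R::norm_rand() / std::sqrt(post_prec);
      }
    // population precisions: conjugate gamma
    for (int s = 0; s < n_stages; ++s)
      for (int k = 0; k < P; ++k) {
        double ss = 0.0, m = mu[s * P + k];
        for (int u = 0; u < n_units; ++u)
          if (unit_stage[u] == s) {
            double e = beta[u * P + k] - m;
            ss += e * e;
          }
        tau[s * P + k] = R::rgamma(tau_shape + 0.5 * stage_n[s],
                                   1.0 / (tau_rate + 0.5 * ss));
      }
    // interweaved non-centered mean update: with the unit deviations
    // (beta_u - mu) held fixed, translate mu and every unit coefficient
    // of the stage together against the likelihood.  When sigma is
    // small the centered Gibbs step moves mu only in O(sigma/sqrt(n))
    // increments; this move takes likelihood-sized steps instead.
    for (int s = 0; s < n_stages; ++s)
      for (int k = 0; k < P; ++k) {
        const int sk = s * P + k;
        const double* xk = xp + (size_t)k * nr;
        double d = R::norm_rand() * mscale[sk];
        double m = mu[sk], mnew = m + d;
        double dll = -0.5 * prec0 * ((mnew - mu0) * (mnew - mu0) -
                                     (m - mu0) * (m - mu0));
        for (int u = 0; u < n_units; ++u) {
          if (unit_stage[u] != s) continue;
          const std::vector<int>& sets = usets[u];
          for (size_t j = 0; j < sets.size(); ++j) {
            const int i = sets[j];
            Vp[0] = V[3 * i]     + d * xk[3 * i];
            Vp[1] = V[3 * i + 1] + d * xk[3 * i + 1];
            Vp[2] = V[3 * i + 2] + d * xk[3 * i + 2];
            prop[i] = set_ll(&Vp[0], used[i]);
            dll += prop[i] - cur[i];
          }
        }
        ++mtries[sk];
        if (std::log(R::unif_rand()) < dll) {
          mu[sk] = mnew;
          for (int u = 0; u < n_units; ++u) {
            if (unit_stage[u] != s) continue;
            beta[u * P + k] += d;
            const std::vector<int>& sets = usets[u];
            for (size_t j = 0; j < sets.size(); ++j) {
              const int i = sets[j];
              V[3 * i]     += d * xk[3 * i];
              V[3 * i + 1] += d * xk[3 * i + 1];
              V[3 * i + 2] += d * xk[3 * i + 2];
              cur[i] = prop[i];
            }
          }
          ++macc[sk];
        }
      }
    // interweaved non-centered precision update: with eta_u = (beta_u -
    // mu) sqrt(tau) held fixed, a Metropolis move on log tau rescales
    // every unit's deviation at once, letting the chain cross the
    // sigma ~ 0 funnel that the centered Gibbs step alone cannot leave.
    for (int s = 0; s < n_stages; ++s)
      for (int k = 0; k < P; ++k) {
        const int sk = s * P + k;
        const double* xk = xp + (size_t)k * nr;
        double ltau = std::log(tau[sk]);
        double lnew = ltau + R::norm_rand() * tscale[sk];
        double sd_old = std::exp(-0.5 * ltau), sd_new = std::exp(-0.5 * lnew);
        double m = mu[sk];
        // p(log tau) from Gamma(shape, rate) prior plus Jacobian
        double dll = tau_shape * (lnew - ltau) -
          tau_rate * (std::exp(lnew) - std::exp(ltau));
        for (int u = 0; u < n_units; ++u) {
          if (unit_stage[u] != s) continue;
          double eta = (beta[u * P + k] - m) / sd_old;
          double d = eta * (sd_new - sd_old);
          const std::vector<int>& sets = usets[u];
          for (size_t j = 0; j < sets.size(); ++j) {
            const int i = sets[j];
            Vp[0] = V[3 * i]     + d * xk[3 * i];
            Vp[1] = V[3 * i + 1] + d * xk[3 * i + 1];
            Vp[2] = V[3 * i + 2] + d * xk[3 * i + 2];
            prop[i] = set_ll(&Vp[0], used[i]);
            dll += prop[i] - cur[i];
          }
        }
        ++ttries[sk];
        if (std::log(R::unif_rand()) < dll) {
          for (int u = 0; u < n_units; ++u) {
            if (unit_stage[u] != s) continue;
            double eta = (beta[u * P + k] - m) / sd_old;
            double d = eta * (sd_new - sd_old);
            beta[u * P + k] = m + eta * sd_new;
            const std::vector<int>& sets = usets[u];
            for (size_t j = 0; j < sets.size(); ++j) {
              const int i = sets[j];
              V[3 * i]     += d * xk[3 * i];
              V[3 * i + 1] += d * xk[3 * i + 1];
              V[3 * i + 2] += d * xk[3 * i + 2];
              cur[i] = prop[i];
            }
          }
          tau[sk] = std::exp(lnew);
          ++tacc[sk];
        }
      }
    if (it <= n_burnin && it % adapt_interval == 0) {
      for (int idx = 0; idx < n_units * P; ++idx) {
        double rate = tries[idx] ? (double)acc[idx] / tries[idx] : 0.0;
        if (rate > 0.44) scale[idx] *= 1.4;
        else if (rate < 0.23) scale[idx] /= 1.4;
        acc[idx] = tries[idx] = 0;
      }
      for (int sk = 0; sk < n_stages * P; ++sk) {
        double rate = ttries[sk] ? (double)tacc[sk] / ttries[sk] : 0.0;
        if (rate > 0.44) tscale[sk] *= 1.4;
        else if (rate < 0.23) tscale[sk] /= 1.4;
        tacc[sk] = ttries[sk] = 0;
        rate = mtries[sk] ? (double)macc[sk] / mtries[sk] : 0.0;
        if (rate > 0.44) mscale[sk] *= 1.4;
        else if (rate < 0.23) mscale[sk] /= 1.4;
        macc[sk] = mtries[sk] = 0;
      }
    }
    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      for (int j = 0; j < n_stages * P; ++j) {
        out_mu(kept, j) = mu[j];
        out_sd(kept, j) = 1.0 / std::sqrt(tau[j]);
      }
      for (int j = 0; j < n_units * P; ++j) out_beta(kept, j) = beta[j];
      ++kept;
    }
  }
  return List::create(_["mu"] = out_mu, _["sigma"] = out_sd,
                      _["beta"] = out_beta);
}
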