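#include "pvl.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared machinery for the three Metropolis-within-Gibbs samplers.
//
// All samplers share the same continuous-state moves:
//   * individual probit-scale parameters z_ij: random-walk Metropolis against
//     the compiled PVL-Delta likelihood (direct Gibbs from the hierarchical
//     normal when the likelihood is switched off for prior calibration);
//   * group-level means: conjugate normal draws;
//   * group-level SDs: reflected random-walk Metropolis.
// Proposal scales adapt in batches of 50 during burn-in only (targeting an
// acceptance rate of 0.44), then stay fixed, so the retained chain is a
// valid time-homogeneous Markov chain.
// ---------------------------------------------------------------------------

namespace {

struct SubjectData {
  std::vector<std::vector<int> > deck;
  std::vector<std::vector<double> > net;
  int n;
};

SubjectData unpack_subjects(List decks, List nets) {
  SubjectData s;
  s.n = decks.size();
  s.deck.resize(s.n);
  s.net.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    IntegerVector d = decks[i];
    NumericVector x = nets[i];
    s.deck[i].assign(d.begin(), d.end());
    s.net[i].assign(x.begin(), x.end());
  }
  return s;
}

inline double ldnorm(double x, double m, double s) {
  return R::dnorm(x, m, s, 1);
}

// Reflect a proposal into (lo, hi); symmetric, preserves detailed balance.
inline double reflect(double x, double lo, double hi) {
  const double range = hi - lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
    (void)range;
  }
  return x;
}

struct AdaptScale {
  double step;
  int acc, tries;
  explicit AdaptScale(double s0 = 0.25) : step(s0), acc(0), tries(0) {}
  void tally(bool accepted) { ++tries; if (accepted) ++acc; }
  void adapt() {
    if (tries == 0) return;
    const double rate = (double)acc / (double)tries;
    double f = std::exp(rate - 0.44);
    if (f < 0.6) f = 0.6;
    if (f > 1.6) f = 1.6;
    step *= f;
    if (step < 1e-3) step = 1e-3;
    if (step > 5.0) step = 5.0;
    acc = 0; tries = 0;
  }
};

// One Metropolis update of coordinate j of subject i's probit parameters.
// Returns true on acceptance; keeps the cached log-likelihood current.
inline bool update_z_coord(const SubjectData& dat, int i, int j,
                           double* zi, double& ll_i,
                           double prior_mean, double prior_sd,
                           double step, double scale, bool use_lik) {
  const double z_old = zi[j];
  const double z_new = z_old + step * R::norm_rand();
  double logr = ldnorm(z_new, prior_mean, prior_sd) -
                ldnorm(z_old, prior_mean, prior_sd);
  double ll_new = ll_i;
  if (use_lik) {
    zi[j] = z_new;
    ll_new = subject_loglik_probit(dat.deck[i], dat.net[i], zi, scale);
    zi[j] = z_old;
    logr += ll_new - ll_i;
  }
  if (std::log(R::unif_rand()) < logr) {
    zi[j] = z_new;
    ll_i = ll_new;
    return true;
  }
  return false;
}

// Conjugate draw for a normal mean: prior N(m0, s0), data z_1..z_n iid
// N(mu, sigma) with sigma known.
inline double conj_normal_mean(const std::vector<double>& z, double sigma,
                               double m0, double s0) {
  const double prec0 = 1.0 / (s0 * s0);
  const double precd = (double)z.size() / (sigma * sigma);
  double sum = 0.0;
  for (size_t i = 0; i < z.size(); ++i) sum += z[i];
  const double prec = prec0 + precd;
  const double mean = (m0 * prec0 + sum / (sigma * sigma)) / prec;
  return mean + R::norm_rand() / std::sqrt(prec);
}

// Log marginal likelihood of z_1..z_n iid N(mu, sigma) with the mean
// integrated out under its N(0,1) prior (sigma known).
inline double lmarg_normal_mean(const std::vector<double>& z, double sigma) {
  const int n = (int)z.size();
  if (n == 0) return 0.0;
  const double s2 = sigma * sigma;
  double sum = 0.0, sumsq = 0.0;
  for (int i = 0; i < n; ++i) { sum += z[i]; sumsq += z[i] * z[i]; }
  const double A = n / s2 + 1.0;        // posterior precision of the mean
  const double b = sum / s2;
  return -0.5 * n * std::log(2.0 * M_PI * s2) - 0.5 * sumsq / s2 -
         0.5 * std::log(A) + 0.5 * b * b / A;
}

// Exact Gibbs draw of a normal SD under a U(0, upper) prior: with
// S = sum (z_i - mu)^2 the full conditional of sigma^2 is inverse-gamma
// ((n-1)/2, S/2) truncated to (0, upper^2); sampled by inverse CDF on the
// corresponding gamma. Eliminates the sticky random walk in the
// sigma <-> individual-parameter funnel.
inline double conj_sigma_uniform(double S, int n, double upper) {
  const double a = 0.5 * (n - 1.0);
  const double b = 0.5 * S;
  if (a <= 0.0 || b <= 0.0) return R::unif_rand() * upper;
  const double xlo = 1.0 / (upper * upper);  // sigma < upper <=> X > xlo
  const double plo = R::pgamma(xlo, a, 1.0 / b, 1, 0);
  double u = plo + (1.0 - plo) * R::unif_rand();
  if (u >= 1.0) u = 1.0 - 1e-15;
  const double x = R::qgamma(u, a, 1.0 / b, 1, 0);
  double sigma = 1.0 / std::sqrt(x);
  if (!std::isfinite(sigma) || sigma <= 0.0) sigma = upper * 0.5;
  if (sigma >= upper) sigma = upper * (1.0 - 1e-12);
  return sigma;
}

} // namespace

// ---------------------------------------------------------------------------
// Hierarchical PVL-Delta sampler for one group.
//
// Model: z'_ij ~ N(mu_j, sigma_j), mu_j ~ N(0,1), sigma_j ~ U(0, sigma_upper),
// choices ~ PVL-Delta(probit^-1(z'_i)). With use_lik = FALSE the chain
// samples the prior exactly (z'_ij drawn by Gibbs).
//
// Returns draws as an array (chain, iteration, parameter) with parameters
// ordered mu[4], sigma[4], then z'_ij for i = 1..n (A, w, a, c within i).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List fit_hier_cpp(List decks, List nets, int nchains, int nburn, int nretain,
                  bool use_lik, double scale, double sigma_upper) {
  SubjectData dat = unpack_subjects(decks, nets);
  const int n = dat.n;
  const int npar = 8 + 4 * n;
  NumericVector out((R_xlen_t)nchains * nretain * npar);
  const int niter = nburn + nretain;

  for (int ch = 0; ch < nchains; ++ch) {
    // random starting values
    double mu[4], sigma[4];
    std::vector<std::vector<double> > z(n, std::vector<double>(4));
    std::vector<double> ll(n, 0.0);
    for (int j = 0; j < 4; ++j) {
      mu[j] = R::norm_rand();
      sigma[j] = R::unif_rand() * (sigma_upper - 0.05) + 0.05;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < 4; ++j) z[i][j] = mu[j] + sigma[j] * R::norm_rand();
      if (use_lik)
        ll[i] = subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
    }
    std::vector<AdaptScale> step_z(n * 4, AdaptScale(0.25));
    std::vector<AdaptScale> step_nc(8, AdaptScale(0.15));

    for (int it = 0; it < niter; ++it) {
      // individual parameters
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < 4; ++j) {
          if (use_lik) {
            bool acc = update_z_coord(dat, i, j, z[i].data(), ll[i],
                                      mu[j], sigma[j],
                                      step_z[i * 4 + j].step, scale, true);
            step_z[i * 4 + j].tally(acc);
          } else {
            z[i][j] = mu[j] + sigma[j] * R::norm_rand();
          }
        }
      }
      // group-level means and SDs: both exact Gibbs
      for (int j = 0; j < 4; ++j) {
        std::vector<double> zj(n);
        for (int i = 0; i < n; ++i) zj[i] = z[i][j];
        mu[j] = conj_normal_mean(zj, sigma[j], 0.0, 1.0);
        double S = 0.0;
        for (int i = 0; i < n; ++i)
          S += (zj[i] - mu[j]) * (zj[i] - mu[j]);
        sigma[j] = conj_sigma_uniform(S, n, sigma_upper);
      }

      // interweaved non-centered moves: holding epsilon_i = (z_i - mu)/sigma
      // fixed, jointly propose (sigma_j) and (mu_j); breaks the funnel
      // between group-level SDs and individual parameters when the
      // likelihood is weakly informative
      if (use_lik) {
        for (int j = 0; j < 4; ++j) {
          // sigma move (prior uniform; epsilon prior unchanged)
          {
            const double s_new =
              reflect(sigma[j] + step_nc[j].step * R::norm_rand(),
                      0.0, sigma_upper);
            std::vector<double> z_new(n), ll_new(n);
            double logr = 0.0;
            for (int i = 0; i < n; ++i) {
              const double eps = (z[i][j] - mu[j]) / sigma[j];
              z_new[i] = mu[j] + s_new * eps;
              const double keep = z[i][j];
              z[i][j] = z_new[i];
              ll_new[i] =
                subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
              z[i][j] = keep;
              logr += ll_new[i] - ll[i];
            }
            const bool acc = std::log(R::unif_rand()) < logr;
            if (acc) {
              sigma[j] = s_new;
              for (int i = 0; i < n; ++i) { z[i][j] = z_new[i]; ll[i] = ll_new[i]; }
            }
            step_nc[j].tally(acc);
          }
          // mu move (translates every z_ij; prior N(0,1) on mu)
          {
            const double m_new = mu[j] + step_nc[4 + j].step * R::norm_rand();
            const double shift = m_new - mu[j];
            std::vector<double> ll_new(n);
            double logr = ldnorm(m_new, 0.0, 1.0) - ldnorm(mu[j], 0.0, 1.0);
            for (int i = 0; i < n; ++i) {
              z[i][j] += shift;
              ll_new[i] =
                subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
              z[i][j] -= shift;
              logr += ll_new[i] - ll[i];
            }
            const bool acc = std::log(R::unif_rand()) < logr;
            if (acc) {
              mu[j] = m_new;
              for (int i = 0; i < n; ++i) { z[i][j] += shift; ll[i] = ll_new[i]; }
            }
            step_nc[4 + j].tally(acc);
          }
        }
      }

      // burn-in adaptation
      if (it < nburn && (it + 1) % 50 == 0) {
        for (size_t k = 0; k < step_z.size(); ++k) step_z[k].adapt();
        for (size_t k = 0; k < step_nc.size(); ++k) step_nc[k].adapt();
      }
      // store
      if (it >= nburn) {
        const int rit = it - nburn;
        const R_xlen_t base = ch + (R_xlen_t)nchains * rit;
        const R_xlen_t stride = (R_xlen_t)nchains * nretain;
        for (int j = 0; j < 4; ++j) out[base + stride * j] = mu[j];
        for (int j = 0; j < 4; ++j) out[base + stride * (4 + j)] = sigma[j];
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < 4; ++j)
            out[base + stride * (8 + 4 * i + j)] = z[i][j];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nchains, nretain, npar);
  return List::create(_["draws"] = out);
}

// ---------------------------------------------------------------------------
// Product-space (Carlin-Chib) sampler over the 16 group-difference models.
//
// Four independent binary indicators gamma_j (prior Bernoulli(1/2) each, so
// every one of the 16 models has prior probability 1/16). Under gamma_j = 0
// both groups share mu0_j; under gamma_j = 1 the groups have mu1_j, mu2_j.
// Group-level SDs sigma_j are always shared. Inactive means are drawn from
// moment-matched pseudo-priors (pm, ps columns: pooled, group1, group2) and
// the indicators are updated by their exact full conditionals, which
// factorize over j; the per-sweep conditional probabilities are returned so
// the caller can Rao-Blackwellize the posterior model probabilities.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List fit_pspace_cpp(List decks, List nets, IntegerVector grp,
                    NumericMatrix pseudo_mean, NumericMatrix pseudo_sd,
                    int nchains, int nburn, int nretain,
                    bool use_lik, double scale, double sigma_upper) {
  SubjectData dat = unpack_subjects(decks, nets);
  const int n = dat.n;
  const int niter = nburn + nretain;

  IntegerMatrix model_trace(nchains, nretain);       // 0..15 (bit j = gamma_j)
  NumericVector p1_trace((R_xlen_t)nchains * nretain * 4);
  NumericVector rb_trace((R_xlen_t)nchains * nretain * 16);
  NumericVector par_trace((R_xlen_t)nchains * nretain * 16); // mu0,mu1,mu2,sigma
  IntegerVector nswitch(nchains);

  for (int ch = 0; ch < nchains; ++ch) {
    double mu0[4], mu1[4], mu2[4], sigma[4];
    int gamma[4];
    std::vector<std::vector<double> > z(n, std::vector<double>(4));
    std::vector<double> ll(n, 0.0);
    for (int j = 0; j < 4; ++j) {
      mu0[j] = R::norm_rand();
      mu1[j] = R::norm_rand();
      mu2[j] = R::norm_rand();
      sigma[j] = R::unif_rand() * (sigma_upper - 0.05) + 0.05;
      gamma[j] = (R::unif_rand() < 0.5) ? 1 : 0;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < 4; ++j) {
        const double m = gamma[j] ? (grp[i] == 1 ? mu1[j] : mu2[j]) : mu0[j];
        z[i][j] = m + sigma[j] * R::norm_rand();
      }
      if (use_lik)
        ll[i] = subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
    }
    std::vector<AdaptScale> step_z(n * 4, AdaptScale(0.25));
    std::vector<AdaptScale> step_nc(8, AdaptScale(0.15));
    int prev_model = -1;

    for (int it = 0; it < niter; ++it) {
      // Each stored sweep runs `ncycle` full update cycles (individual
      // parameters, then shared SDs, collapsed indicators and group means);
      // the Rao-Blackwellized indicator conditionals are averaged over the
      // cycles. More indicator updates per stored draw cuts both the
      // autocorrelation and the Monte Carlo noise of the model
      // probabilities.
      const int ncycle = use_lik ? 3 : 1;
      double p1[4] = {0.0, 0.0, 0.0, 0.0};
      double rb[16];
      for (int m = 0; m < 16; ++m) rb[m] = 0.0;
      for (int cyc = 0; cyc < ncycle; ++cyc) {
        double p1c[4];
        for (int i = 0; i < n; ++i) {
          for (int j = 0; j < 4; ++j) {
            const double m = gamma[j] ? (grp[i] == 1 ? mu1[j] : mu2[j]) : mu0[j];
            if (use_lik) {
              bool acc = update_z_coord(dat, i, j, z[i].data(), ll[i],
                                        m, sigma[j],
                                        step_z[i * 4 + j].step, scale, true);
              step_z[i * 4 + j].tally(acc);
            } else {
              z[i][j] = m + sigma[j] * R::norm_rand();
            }
          }
        }

        for (int j = 0; j < 4; ++j) {
          std::vector<double> zall, z1, z2;
          for (int i = 0; i < n; ++i) {
            zall.push_back(z[i][j]);
            if (grp[i] == 1) z1.push_back(z[i][j]); else z2.push_back(z[i][j]);
          }
          // shared SD: exact Gibbs under the currently active means
          double S = 0.0;
          for (int i = 0; i < n; ++i) {
            const double m = gamma[j] ? (grp[i] == 1 ? mu1[j] : mu2[j]) : mu0[j];
            S += (z[i][j] - m) * (z[i][j] - m);
          }
          sigma[j] = conj_sigma_uniform(S, n, sigma_upper);

          // partially collapsed indicator update: the group-level means are
          // integrated out analytically (normal marginal likelihoods under
          // the N(0,1) prior), so the conditional depends only on
          // (z, sigma); the pseudo-priors cancel in this collapsed
          // conditional
          const double lw1 = std::log(0.5) +
            lmarg_normal_mean(z1, sigma[j]) + lmarg_normal_mean(z2, sigma[j]);
          const double lw0 = std::log(0.5) + lmarg_normal_mean(zall, sigma[j]);
          const double mx = std::max(lw0, lw1);
          const double p1_now =
            std::exp(lw1 - mx) / (std::exp(lw0 - mx) + std::exp(lw1 - mx));
          p1c[j] = p1_now;
          p1[j] += p1_now / ncycle;
          gamma[j] = (R::unif_rand() < p1_now) ? 1 : 0;

          // group-level means given the (possibly new) indicator: active
          // means conjugate, inactive means from their moment-matched
          // pseudo-priors
          if (gamma[j]) {
            mu1[j] = conj_normal_mean(z1, sigma[j], 0.0, 1.0);
            mu2[j] = conj_normal_mean(z2, sigma[j], 0.0, 1.0);
            mu0[j] = pseudo_mean(j, 0) + pseudo_sd(j, 0) * R::norm_rand();
          } else {
            mu0[j] = conj_normal_mean(zall, sigma[j], 0.0, 1.0);
            mu1[j] = pseudo_mean(j, 1) + pseudo_sd(j, 1) * R::norm_rand();
            mu2[j] = pseudo_mean(j, 2) + pseudo_sd(j, 2) * R::norm_rand();
          }
        }
        // Rao-Blackwellized joint model probabilities for this cycle:
        // product over the four conditionally independent indicators
        for (int m = 0; m < 16; ++m) {
          double w = 1.0;
          for (int j = 0; j < 4; ++j)
            w *= ((m >> j) & 1) ? p1c[j] : 1.0 - p1c[j];
          rb[m] += w / ncycle;
        }
      }

      // interweaved non-centered moves on the active means / shared SDs
      if (use_lik) {
        for (int j = 0; j < 4; ++j) {
          // sigma move: rescale every z_ij around its active mean
          {
            const double s_new =
              reflect(sigma[j] + step_nc[j].step * R::norm_rand(),
                      0.0, sigma_upper);
            std::vector<double> z_new(n), ll_new(n);
            double logr = 0.0;
            for (int i = 0; i < n; ++i) {
              const double m = gamma[j] ? (grp[i] == 1 ? mu1[j] : mu2[j]) : mu0[j];
              z_new[i] = m + s_new * (z[i][j] - m) / sigma[j];
              const double keep = z[i][j];
              z[i][j] = z_new[i];
              ll_new[i] =
                subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
              z[i][j] = keep;
              logr += ll_new[i] - ll[i];
            }
            const bool acc = std::log(R::unif_rand()) < logr;
            if (acc) {
              sigma[j] = s_new;
              for (int i = 0; i < n; ++i) { z[i][j] = z_new[i]; ll[i] = ll_new[i]; }
            }
            step_nc[j].tally(acc);
          }
          // mean moves: translate the subjects governed by each active mean
          const int nmoves = gamma[j] ? 2 : 1;
          for (int mv = 0; mv < nmoves; ++mv) {
            double* mtarget = gamma[j] ? (mv == 0 ? &mu1[j] : &mu2[j]) : &mu0[j];
            const double m_new = *mtarget + step_nc[4 + j].step * R::norm_rand();
            const double shift = m_new - *mtarget;
            double logr = ldnorm(m_new, 0.0, 1.0) - ldnorm(*mtarget, 0.0, 1.0);
            std::vector<double> ll_new(n);
            std::vector<bool> moved(n, false);
            for (int i = 0; i < n; ++i) {
              const bool affected = !gamma[j] || grp[i] == (mv == 0 ? 1 : 2);
              if (!affected) { ll_new[i] = ll[i]; continue; }
              moved[i] = true;
              z[i][j] += shift;
              ll_new[i] =
                subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
              z[i][j] -= shift;
              logr += ll_new[i] - ll[i];
            }
            const bool acc = std::log(R::unif_rand()) < logr;
            if (acc) {
              *mtarget = m_new;
              for (int i = 0; i < n; ++i)
                if (moved[i]) { z[i][j] += shift; ll[i] = ll_new[i]; }
            }
            step_nc[4 + j].tally(acc);
          }
        }
      }

      if (it < nburn && (it + 1) % 50 == 0) {
        for (size_t k = 0; k < step_z.size(); ++k) step_z[k].adapt();
        for (size_t k = 0; k < step_nc.size(); ++k) step_nc[k].adapt();
      }

      if (it >= nburn) {
        const int rit = it - nburn;
        int model = 0;
        for (int j = 0; j < 4; ++j) model |= gamma[j] << j;
        model_trace(ch, rit) = model;
        if (prev_model >= 0 && model != prev_model) ++nswitch[ch];
        prev_model = model;
        const R_xlen_t base = ch + (R_xlen_t)nchains * rit;
        const R_xlen_t stride = (R_xlen_t)nchains * nretain;
        for (int j = 0; j < 4; ++j) {
          p1_trace[base + stride * j] = p1[j];
          par_trace[base + stride * j] = mu0[j];
          par_trace[base + stride * (4 + j)] = mu1[j];
          par_trace[base + stride * (8 + j)] = mu2[j];
          par_trace[base + stride * (12 + j)] = sigma[j];
        }
        for (int m = 0; m < 16; ++m)
          rb_trace[base + stride * m] = rb[m];
      }
    }
  }
  p1_trace.attr("dim") = IntegerVector::create(nchains, nretain, 4);
  rb_trace.attr("dim") = IntegerVector::create(nchains, nretain, 16);
  par_trace.attr("dim") = IntegerVector::create(nchains, nretain, 16);
  return List::create(_["model_trace"] = model_trace,
                      _["p1_trace"] = p1_trace,
                      _["rb_trace"] = rb_trace,
                      _["par_trace"] = par_trace,
                      _["n_switches"] = nswitch);
}

// ---------------------------------------------------------------------------
// Two-component latent-mixture sampler with group-specific priors.
//
// zi_i ~ Bernoulli(psi), psi ~ U(0,1); within component g the individual
// probit parameters are N(mu_gj, sigma_gj). Priors on mu_gj are normal
// (mu_prior_mean/sd, rows = component); priors on sigma_gj are either
// zero-truncated normals (sigma_prior_type = 1, informed) or U(0, sigma_upper)
// (sigma_prior_type = 0, the un-informed stage-1 variant). The membership
// indicators are updated by their exact full conditionals; the per-sweep
// conditional probabilities are returned for Rao-Blackwellized posterior
// means of zi_i.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List fit_mixture_cpp(List decks, List nets,
                     NumericMatrix mu_prior_mean, NumericMatrix mu_prior_sd,
                     NumericMatrix sig_prior_mean, NumericMatrix sig_prior_sd,
                     int sigma_prior_type, double sigma_upper,
                     int nchains, int nburn, int nretain,
                     bool use_lik, double scale) {
  SubjectData dat = unpack_subjects(decks, nets);
  const int n = dat.n;
  const int niter = nburn + nretain;

  NumericVector pzi_trace((R_xlen_t)nchains * nretain * n);
  NumericVector psi_trace((R_xlen_t)nchains * nretain);
  NumericVector mu_trace((R_xlen_t)nchains * nretain * 8);   // comp1 then comp2
  NumericVector sig_trace((R_xlen_t)nchains * nretain * 8);

  for (int ch = 0; ch < nchains; ++ch) {
    double mu[2][4], sigma[2][4], psi;
    std::vector<int> zi(n);
    std::vector<std::vector<double> > z(n, std::vector<double>(4));
    std::vector<double> ll(n, 0.0);
    psi = R::unif_rand();
    for (int g = 0; g < 2; ++g)
      for (int j = 0; j < 4; ++j) {
        mu[g][j] = mu_prior_mean(g, j) + mu_prior_sd(g, j) * R::norm_rand();
        if (sigma_prior_type == 1) {
          double s;
          do {
            s = sig_prior_mean(g, j) + sig_prior_sd(g, j) * R::norm_rand();
          } while (s <= 0.0);
          sigma[g][j] = s;
        } else {
          sigma[g][j] = R::unif_rand() * (sigma_upper - 0.05) + 0.05;
        }
      }
    for (int i = 0; i < n; ++i) {
      zi[i] = (R::unif_rand() < psi) ? 1 : 0;
      for (int j = 0; j < 4; ++j)
        z[i][j] = mu[zi[i]][j] + sigma[zi[i]][j] * R::norm_rand();
      if (use_lik)
        ll[i] = subject_loglik_probit(dat.deck[i], dat.net[i], z[i].data(), scale);
    }
    std::vector<AdaptScale> step_z(n * 4, AdaptScale(0.25));
    std::vector<AdaptScale> step_s(8, AdaptScale(0.1));

    for (int it = 0; it < niter; ++it) {
      std::vector<double> pzi(n);
      int n2 = 0;
      if (use_lik) {
        // individual parameters under the currently assigned component
        for (int i = 0; i < n; ++i) {
          const int g = zi[i];
          for (int j = 0; j < 4; ++j) {
            bool acc = update_z_coord(dat, i, j, z[i].data(), ll[i],
                                      mu[g][j], sigma[g][j],
                                      step_z[i * 4 + j].step, scale, true);
            step_z[i * 4 + j].tally(acc);
          }
        }
        // membership indicators: exact full conditional (the choice
        // likelihood depends on zi only through the individual parameters,
        // which are conditioned on, so only the component densities and psi
        // enter)
        for (int i = 0; i < n; ++i) {
          double lw1 = std::log(psi), lw0 = std::log1p(-psi);
          for (int j = 0; j < 4; ++j) {
            lw1 += ldnorm(z[i][j], mu[1][j], sigma[1][j]);
            lw0 += ldnorm(z[i][j], mu[0][j], sigma[0][j]);
          }
          const double mx = std::max(lw0, lw1);
          pzi[i] = std::exp(lw1 - mx) / (std::exp(lw0 - mx) + std::exp(lw1 - mx));
          zi[i] = (R::unif_rand() < pzi[i]) ? 1 : 0;
          n2 += zi[i];
        }
      } else {
        // prior calibration: blocked Gibbs. With the likelihood off, nothing
        // constrains the individual parameters, so zi is drawn with them
        // marginalized out -- its conditional is exactly Bernoulli(psi) --
        // and the parameters are then refreshed from the assigned component
        // before anything else conditions on them. A single-site update
        // would freeze here whenever the two components barely overlap.
        for (int i = 0; i < n; ++i) {
          pzi[i] = psi;
          zi[i] = (R::unif_rand() < psi) ? 1 : 0;
          n2 += zi[i];
          for (int j = 0; j < 4; ++j)
            z[i][j] = mu[zi[i]][j] + sigma[zi[i]][j] * R::norm_rand();
        }
      }
      psi = R::rbeta(1.0 + n2, 1.0 + (n - n2));

      // component-level parameters
      for (int g = 0; g < 2; ++g) {
        for (int j = 0; j < 4; ++j) {
          std::vector<double> zg;
          for (int i = 0; i < n; ++i) if (zi[i] == g) zg.push_back(z[i][j]);
          if (zg.empty()) {
            // no members: full conditional is the prior
            mu[g][j] = mu_prior_mean(g, j) + mu_prior_sd(g, j) * R::norm_rand();
          } else {
            mu[g][j] = conj_normal_mean(zg, sigma[g][j],
                                        mu_prior_mean(g, j), mu_prior_sd(g, j));
          }
          // SD: exact Gibbs under the uniform prior; positive random walk
          // under the zero-truncated normal prior
          if (sigma_prior_type == 0 && zg.size() >= 2) {
            double S = 0.0;
            for (size_t i2 = 0; i2 < zg.size(); ++i2)
              S += (zg[i2] - mu[g][j]) * (zg[i2] - mu[g][j]);
            sigma[g][j] = conj_sigma_uniform(S, (int)zg.size(), sigma_upper);
          } else if (sigma_prior_type == 0) {
            // 0 or 1 members: empty -> conditional is the U(0, upper) prior;
            // single member -> reflected random-walk Metropolis
            if (zg.empty()) {
              sigma[g][j] = R::unif_rand() * sigma_upper;
            } else {
              const double s_old = sigma[g][j];
              const double s_new =
                reflect(s_old + step_s[g * 4 + j].step * R::norm_rand(),
                        0.0, sigma_upper);
              const double logr = ldnorm(zg[0], mu[g][j], s_new) -
                                  ldnorm(zg[0], mu[g][j], s_old);
              const bool acc = std::log(R::unif_rand()) < logr;
              if (acc) sigma[g][j] = s_new;
              step_s[g * 4 + j].tally(acc);
            }
          } else {
            const double s_old = sigma[g][j];
            double s_new = s_old + step_s[g * 4 + j].step * R::norm_rand();
            if (s_new < 0.0) s_new = -s_new;  // reflect at 0 only
            double logr =
              ldnorm(s_new, sig_prior_mean(g, j), sig_prior_sd(g, j)) -
              ldnorm(s_old, sig_prior_mean(g, j), sig_prior_sd(g, j));
            for (size_t i2 = 0; i2 < zg.size(); ++i2)
              logr += ldnorm(zg[i2], mu[g][j], s_new) -
                      ldnorm(zg[i2], mu[g][j], s_old);
            const bool acc = std::log(R::unif_rand()) < logr;
            if (acc) sigma[g][j] = s_new;
            step_s[g * 4 + j].tally(acc);
          }
        }
      }

      if (it < nburn && (it + 1) % 50 == 0) {
        for (size_t k = 0; k < step_z.size(); ++k) step_z[k].adapt();
        for (size_t k = 0; k < step_s.size(); ++k) step_s[k].adapt();
      }

      if (it >= nburn) {
        const int rit = it - nburn;
        const R_xlen_t base = ch + (R_xlen_t)nchains * rit;
        const R_xlen_t stride = (R_xlen_t)nchains * nretain;
        psi_trace[base] = psi;
        for (int i = 0; i < n; ++i) pzi_trace[base + stride * i] = pzi[i];
        for (int g = 0; g < 2; ++g)
          for (int j = 0; j < 4; ++j) {
            mu_trace[base + stride * (g * 4 + j)] = mu[g][j];
            sig_trace[base + stride * (g * 4 + j)] = sigma[g][j];
          }
      }
    }
  }
  pzi_trace.attr("dim") = IntegerVector::create(nchains, nretain, n);
  psi_trace.attr("dim") = IntegerVector::create(nchains, nretain);
  mu_trace.attr("dim") = IntegerVector::create(nchains, nretain, 8);
  sig_trace.attr("dim") = IntegerVector::create(nchains, nretain, 8);
  return List::create(_["pzi"] = pzi_trace, _["psi"] = psi_trace,
                      _["mu"] = mu_trace, _["sigma"] = sig_trace);
}
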