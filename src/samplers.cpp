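#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// ex-Gaussian log-density, stable for small tau.
//
// f(t) = 1/tau * exp((mu - t)/tau + sigma^2/(2 tau^2)) * Phi((t-mu)/sigma - sigma/tau)
//
// With u = (t-mu)/sigma, k = sigma/tau, x = u - k the exponent is
// k^2/2 - u*k which cancels catastrophically against log Phi(x) when
// x << 0 (tau -> 0).  In that regime we switch to the asymptotic Mills
// ratio expansion, which collapses analytically to a Gaussian density
// times a correction series:
//   log f = -u^2/2 - log(sqrt(2*pi)) - log(sigma - u*tau)
//           + log(1 - 1/x^2 + 3/x^4 - 15/x^6 + 105/x^8 - 945/x^10)
// Truncation error of the series is O(10395/x^12) < 1e-8 for x <= -10.
// ---------------------------------------------------------------------------
static const double LOG_SQRT_2PI = 0.9189385332046727417803297364;

static inline double exgauss_lpdf(double t, double mu, double sigma, double tau) {
  double u = (t - mu) / sigma;
  double k = sigma / tau;
  double x = u - k;
  if (x > -10.0) {
    // direct branch: exponent k^2/2 - u*k <= 10k - k^2/2 <= 50, never overflows
    return -std::log(tau) + 0.5 * k * k - u * k + R::pnorm(x, 0.0, 1.0, 1, 1);
  }
  double x2 = x * x;
  double x4 = x2 * x2, x6 = x4 * x2, x8 = x4 * x4;
  double series = 1.0 - 1.0 / x2 + 3.0 / x4 - 15.0 / x6 + 105.0 / x8 -
                  945.0 / (x8 * x2);
  return -0.5 * u * u - LOG_SQRT_2PI - std::log(sigma - u * tau) +
         std::log(series);
}

// [[Rcpp::export]]
NumericVector exgauss_lpdf_cpp(NumericVector t, double mu, double sigma,
                               double tau) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = exgauss_lpdf(t[i], mu, sigma, tau);
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical ex-Gaussian model, one age group, K conditions.
//
//   rt_{ikj} ~ exGaussian(mu_{ik}, sig_{ik}, tau_{ik})
//   mu_{ik}  ~ Normal(Mmu_k, Smu_k)
//   sig_{ik} ~ Normal(Msig_k, Ssig_k) truncated > 0
//   tau_{ik} ~ Normal(Mtau_k, Stau_k) truncated > 0
//   Mmu_k  ~ Normal(prior_mu_mean, prior_mu_sd) truncated > 0
//   Msig_k, Mtau_k ~ half-Normal(prior_group_scale)
//   Smu_k, Ssig_k, Stau_k ~ half-Normal(prior_sd_scale)
//
// Sampler: adaptive random-walk Metropolis within Gibbs.  Participant cells
// get single-parameter moves plus a correlated (mu + d, tau - d) move that
// tracks the mu/tau trade-off of the ex-Gaussian likelihood.  Group means
// and SDs are updated by adaptive MH (SDs on the log scale), with the
// truncation normalizer Phi(M/S) of the participant priors included, and
// several sweeps per iteration to speed mixing.  Uses R's RNG, so chains
// are reproducible via set.seed() on the R side.
// ---------------------------------------------------------------------------

struct AdaptScale {
  double ls;       // log proposal sd
  int acc, tries;
  AdaptScale() : ls(std::log(0.1)), acc(0), tries(0) {}
};

// Independence move for a hierarchy SD: propose S'^2 ~ InvGamma(n/2 - 1, b)
// with b = sum of squared deviations / 2 (the shape the Normal likelihood
// induces); the Metropolis-Hastings correction then only involves the
// half-Normal prior, the 1/S proposal mismatch, and (for truncated
// families) the Phi(M/S)^(-n) normalizer.  Being an independence sampler it
// relocates S globally, which breaks the slow random-walk drift at the
// mouth of the hierarchical funnel.
static inline double sd_indep_move(double S, double M, const double *th,
                                   int n, double prior_scale, bool trunc) {
  if (n < 5) return S;
  double b = 0.0;
  for (int i = 0; i < n; ++i) b += (th[i] - M) * (th[i] - M);
  b *= 0.5;
  if (b <= 0) return S;
  double g = R::rgamma(0.5 * n - 1.0, 1.0);
  if (g <= 0) return S;
  double Sp = std::sqrt(b / g);
  auto lext = [&](double s) -> double {
    double v = -0.5 * s * s / (prior_scale * prior_scale) - std::log(s);
    if (trunc) v -= n * R::pnorm(M / s, 0, 1, 1, 1);
    return v;
  };
  double lr = lext(Sp) - lext(S);
  if (std::log(R::unif_rand()) < lr) return Sp;
  return S;
}

static inline void adapt(AdaptScale &a, int batch) {
  if (a.tries == 0) return;
  double rate = (double)a.acc / a.tries;
  double delta = std::min(0.25, 2.0 / std::sqrt((double)batch + 1.0));
  a.ls += (rate > 0.44 ? delta : -delta);
  a.ls = std::max(-12.0, std::min(4.0, a.ls));
  a.acc = 0; a.tries = 0;
}

// [[Rcpp::export]]
List exgauss_hier_chain(NumericVector rt, IntegerVector part, IntegerVector cond,
                        int n_part, int n_cond, int n_iter, int n_warmup,
                        List prior, List init, int n_thin = 1) {
  int n = rt.size();
  // trial index lists per participant x condition cell
  std::vector< std::vector<int> > cell(n_part * n_cond);
  for (int j = 0; j < n; ++j) cell[part[j] * n_cond + cond[j]].push_back(j);

  NumericMatrix mu(clone(as<NumericMatrix>(init["mu"])));
  NumericMatrix sig(clone(as<NumericMatrix>(init["sig"])));
  NumericMatrix tau(clone(as<NumericMatrix>(init["tau"])));
  NumericVector Mmu(clone(as<NumericVector>(init["Mmu"])));
  NumericVector Msig(clone(as<NumericVector>(init["Msig"])));
  NumericVector Mtau(clone(as<NumericVector>(init["Mtau"])));
  NumericVector Smu(clone(as<NumericVector>(init["Smu"])));
  NumericVector Ssig(clone(as<NumericVector>(init["Ssig"])));
  NumericVector Stau(clone(as<NumericVector>(init["Stau"])));

  double pr_mu_mean = prior["mu_mean"], pr_mu_sd = prior["mu_sd"];
  double pr_group = prior["group_scale"], pr_sd = prior["sd_scale"];

  // cached per-cell log-likelihoods
  NumericMatrix llik(n_part, n_cond);
  for (int i = 0; i < n_part; ++i)
    for (int k = 0; k < n_cond; ++k) {
      double s = 0.0;
      for (int j : cell[i * n_cond + k])
        s += exgauss_lpdf(rt[j], mu(i, k), sig(i, k), tau(i, k));
      llik(i, k) = s;
    }

  // adaptive scales: 4 move types per cell, 5 MH group params per condition,
  // 6 parameter-expansion moves per condition (translate/rescale x mu/sig/tau)
  std::vector<AdaptScale> sc_cell(n_part * n_cond * 4);
  std::vector<AdaptScale> sc_grp(n_cond * 5);
  std::vector<AdaptScale> sc_exp(n_cond * 6);
  for (size_t q = 0; q < sc_cell.size(); ++q) sc_cell[q].ls = std::log(0.15);
  for (size_t q = 0; q < sc_grp.size(); ++q) sc_grp[q].ls = std::log(0.05);
  for (size_t q = 0; q < sc_exp.size(); ++q) sc_exp[q].ls = std::log(0.1);

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, 6 * n_cond);
  int batch = 0;

  for (int it = 0; it < n_iter; ++it) {
   for (int rep = 0; rep < n_thin; ++rep) {
    // --- participant-level updates -------------------------------------
    for (int i = 0; i < n_part; ++i) {
      for (int k = 0; k < n_cond; ++k) {
        std::vector<int> &tr = cell[i * n_cond + k];
        if (tr.empty()) continue;
        int base = (i * n_cond + k) * 4;
        double cmu = mu(i, k), csig = sig(i, k), ctau = tau(i, k);

        // move 0: mu
        {
          AdaptScale &a = sc_cell[base]; a.tries++;
          double p = cmu + R::norm_rand() * std::exp(a.ls);
          double ll = 0.0;
          for (int j : tr) ll += exgauss_lpdf(rt[j], p, csig, ctau);
          double lr = ll - llik(i, k) +
            R::dnorm(p, Mmu[k], Smu[k], 1) - R::dnorm(cmu, Mmu[k], Smu[k], 1);
          if (std::log(R::unif_rand()) < lr) { mu(i, k) = cmu = p; llik(i, k) = ll; a.acc++; }
        }
        // move 1: sigma (> 0)
        {
          AdaptScale &a = sc_cell[base + 1]; a.tries++;
          double p = csig + R::norm_rand() * std::exp(a.ls);
          if (p > 0) {
            double ll = 0.0;
            for (int j : tr) ll += exgauss_lpdf(rt[j], cmu, p, ctau);
            double lr = ll - llik(i, k) +
              R::dnorm(p, Msig[k], Ssig[k], 1) - R::dnorm(csig, Msig[k], Ssig[k], 1);
            if (std::log(R::unif_rand()) < lr) { sig(i, k) = csig = p; llik(i, k) = ll; a.acc++; }
          }
        }
        // move 2: tau (> 0)
        {
          AdaptScale &a = sc_cell[base + 2]; a.tries++;
          double p = ctau + R::norm_rand() * std::exp(a.ls);
          if (p > 0) {
            double ll = 0.0;
            for (int j : tr) ll += exgauss_lpdf(rt[j], cmu, csig, p);
            double lr = ll - llik(i, k) +
              R::dnorm(p, Mtau[k], Stau[k], 1) - R::dnorm(ctau, Mtau[k], Stau[k], 1);
            if (std::log(R::unif_rand()) < lr) { tau(i, k) = ctau = p; llik(i, k) = ll; a.acc++; }
          }
        }
        // move 3: correlated (mu + d, tau - d), preserves the mean mu + tau
        {
          AdaptScale &a = sc_cell[base + 3]; a.tries++;
          double d = R::norm_rand() * std::exp(a.ls);
          double pmu = cmu + d, ptau = ctau - d;
          if (ptau > 0) {
            double ll = 0.0;
            for (int j : tr) ll += exgauss_lpdf(rt[j], pmu, csig, ptau);
            double lr = ll - llik(i, k) +
              R::dnorm(pmu, Mmu[k], Smu[k], 1) - R::dnorm(cmu, Mmu[k], Smu[k], 1) +
              R::dnorm(ptau, Mtau[k], Stau[k], 1) - R::dnorm(ctau, Mtau[k], Stau[k], 1);
            if (std::log(R::unif_rand()) < lr) {
              mu(i, k) = pmu; tau(i, k) = ptau; llik(i, k) = ll; a.acc++;
            }
          }
        }
      }
    }

    // --- group-level updates (3 sweeps) --------------------------------
    for (int sweep = 0; sweep < 3; ++sweep) {
      for (int k = 0; k < n_cond; ++k) {
        int gb = k * 5;
        // Mmu: conjugate Gibbs (prior truncated > 0; rejection resample)
        {
          double prec = 1.0 / (pr_mu_sd * pr_mu_sd), num = pr_mu_mean * prec;
          for (int i = 0; i < n_part; ++i) {
            double w = 1.0 / (Smu[k] * Smu[k]);
            prec += w; num += mu(i, k) * w;
          }
          double pm = num / prec, ps = std::sqrt(1.0 / prec);
          for (int tryi = 0; tryi < 100; ++tryi) {
            double cand = pm + ps * R::norm_rand();
            if (cand > 0) { Mmu[k] = cand; break; }
          }
        }
        // Msig, Mtau: MH with truncation normalizer of participant priors
        for (int which = 0; which < 2; ++which) {
          NumericVector &M = which == 0 ? Msig : Mtau;
          NumericVector &S = which == 0 ? Ssig : Stau;
          NumericMatrix &th = which == 0 ? sig : tau;
          AdaptScale &a = sc_grp[gb + which]; a.tries++;
          double cur = M[k];
          double p = cur + R::norm_rand() * std::exp(a.ls);
          if (p > 0) {
            double lr = -0.5 * (p * p - cur * cur) / (pr_group * pr_group);
            double lz = R::pnorm(p / S[k], 0, 1, 1, 1) -
                        R::pnorm(cur / S[k], 0, 1, 1, 1);
            for (int i = 0; i < n_part; ++i)
              lr += R::dnorm(th(i, k), p, S[k], 1) -
                    R::dnorm(th(i, k), cur, S[k], 1);
            lr -= n_part * lz;
            if (std::log(R::unif_rand()) < lr) { M[k] = p; a.acc++; }
          }
        }
        // Smu, Ssig, Stau: MH on log scale
        for (int which = 0; which < 3; ++which) {
          NumericVector &S = which == 0 ? Smu : (which == 1 ? Ssig : Stau);
          NumericMatrix &th = which == 0 ? mu : (which == 1 ? sig : tau);
          double M = which == 0 ? Mmu[k] : (which == 1 ? Msig[k] : Mtau[k]);
          bool trunc = which > 0;
          AdaptScale &a = sc_grp[gb + 2 + which]; a.tries++;
          double cur = S[k];
          double p = cur * std::exp(R::norm_rand() * std::exp(a.ls));
          double lr = -0.5 * (p * p - cur * cur) / (pr_sd * pr_sd) +
                      std::log(p) - std::log(cur);  // Jacobian
          for (int i = 0; i < n_part; ++i)
            lr += R::dnorm(th(i, k), M, p, 1) - R::dnorm(th(i, k), M, cur, 1);
          if (trunc)
            lr -= n_part * (R::pnorm(M / p, 0, 1, 1, 1) -
                            R::pnorm(M / cur, 0, 1, 1, 1));
          if (std::log(R::unif_rand()) < lr) { S[k] = p; a.acc++; }
        }
        // independence refresh of the group SDs
        Smu[k] = sd_indep_move(Smu[k], Mmu[k], &mu(0, k), n_part, pr_sd, false);
        Ssig[k] = sd_indep_move(Ssig[k], Msig[k], &sig(0, k), n_part, pr_sd, true);
        Stau[k] = sd_indep_move(Stau[k], Mtau[k], &tau(0, k), n_part, pr_sd, true);
      }
    }

    // --- parameter-expansion moves --------------------------------------
    // The hierarchical funnel (small group SD pinning the participant
    // values) mixes poorly under single-site updates; joint translation
    // (theta_i + d, M + d) and rescale (S' = aS, theta_i' = M + a(theta_i - M))
    // moves update a whole parameter family at once.
    for (int k = 0; k < n_cond; ++k) {
      for (int fam = 0; fam < 3; ++fam) {
        NumericMatrix &th = fam == 0 ? mu : (fam == 1 ? sig : tau);
        NumericVector &M = fam == 0 ? Mmu : (fam == 1 ? Msig : Mtau);
        NumericVector &S = fam == 0 ? Smu : (fam == 1 ? Ssig : Stau);
        bool trunc = fam > 0;

        // translation
        {
          AdaptScale &a = sc_exp[k * 6 + fam]; a.tries++;
          double d = R::norm_rand() * std::exp(a.ls);
          double Mp = M[k] + d;
          bool ok = Mp > 0;
          if (ok && trunc)
            for (int i = 0; i < n_part; ++i)
              if (th(i, k) + d <= 0) { ok = false; break; }
          if (ok) {
            double lr = 0.0;
            std::vector<double> newll(n_part);
            for (int i = 0; i < n_part; ++i) {
              double m_i = fam == 0 ? mu(i, k) + d : mu(i, k);
              double s_i = fam == 1 ? sig(i, k) + d : sig(i, k);
              double t_i = fam == 2 ? tau(i, k) + d : tau(i, k);
              double ll = 0.0;
              for (int j : cell[i * n_cond + k])
                ll += exgauss_lpdf(rt[j], m_i, s_i, t_i);
              newll[i] = ll;
              lr += ll - llik(i, k);
            }
            if (fam == 0)
              lr += R::dnorm(Mp, pr_mu_mean, pr_mu_sd, 1) -
                    R::dnorm(M[k], pr_mu_mean, pr_mu_sd, 1);
            else
              lr += -0.5 * (Mp * Mp - M[k] * M[k]) / (pr_group * pr_group) -
                    n_part * (R::pnorm(Mp / S[k], 0, 1, 1, 1) -
                              R::pnorm(M[k] / S[k], 0, 1, 1, 1));
            if (std::log(R::unif_rand()) < lr) {
              M[k] = Mp;
              for (int i = 0; i < n_part; ++i) { th(i, k) += d; llik(i, k) = newll[i]; }
              a.acc++;
            }
          }
        }
        // rescale; the sigma/tau spreads are weakly identified and mix
        // through this move only, so they get several repeats per sweep
        for (int rr = 0; rr < (trunc ? 4 : 1); ++rr) {
          AdaptScale &a = sc_exp[k * 6 + 3 + fam]; a.tries++;
          // 10% of proposals take a 5x step so chains trapped near S ~ 0
          // (where the posterior can spike) escape quickly
          double big = R::unif_rand() < 0.1 ? 5.0 : 1.0;
          double eps = R::norm_rand() * std::exp(a.ls) * big;
          double alpha = std::exp(eps);
          double Sp = S[k] * alpha;
          bool ok = true;
          std::vector<double> thp(n_part);
          for (int i = 0; i < n_part; ++i) {
            thp[i] = M[k] + alpha * (th(i, k) - M[k]);
            if (trunc && thp[i] <= 0) { ok = false; break; }
          }
          if (ok) {
            double lr = eps;  // residual Jacobian/prior-scale term
            std::vector<double> newll(n_part);
            for (int i = 0; i < n_part; ++i) {
              double m_i = fam == 0 ? thp[i] : mu(i, k);
              double s_i = fam == 1 ? thp[i] : sig(i, k);
              double t_i = fam == 2 ? thp[i] : tau(i, k);
              double ll = 0.0;
              for (int j : cell[i * n_cond + k])
                ll += exgauss_lpdf(rt[j], m_i, s_i, t_i);
              newll[i] = ll;
              lr += ll - llik(i, k);
            }
            lr += -0.5 * (Sp * Sp - S[k] * S[k]) / (pr_sd * pr_sd);
            if (trunc)
              lr -= n_part * (R::pnorm(M[k] / Sp, 0, 1, 1, 1) -
                              R::pnorm(M[k] / S[k], 0, 1, 1, 1));
            if (std::log(R::unif_rand()) < lr) {
              S[k] = Sp;
              for (int i = 0; i < n_part; ++i) { th(i, k) = thp[i]; llik(i, k) = newll[i]; }
              a.acc++;
            }
          }
        }
      }
    }
   }  // n_thin sweeps

    // --- adaptation during warmup ---------------------------------------
    if (it < n_warmup && (it + 1) % 25 == 0) {
      ++batch;
      for (size_t q = 0; q < sc_cell.size(); ++q) adapt(sc_cell[q], batch);
      for (size_t q = 0; q < sc_grp.size(); ++q) adapt(sc_grp[q], batch);
      for (size_t q = 0; q < sc_exp.size(); ++q) adapt(sc_exp[q], batch);
    }

    if (it >= n_warmup) {
      int r = it - n_warmup;
      for (int k = 0; k < n_cond; ++k) {
        draws(r, 6 * k + 0) = Mmu[k];
        draws(r, 6 * k + 1) = Msig[k];
        draws(r, 6 * k + 2) = Mtau[k];
        draws(r, 6 * k + 3) = Smu[k];
        draws(r, 6 * k + 4) = Ssig[k];
        draws(r, 6 * k + 5) = Stau[k];
      }
    }
  }
  return List::create(_["draws"] = draws);
}

// ---------------------------------------------------------------------------
// Hierarchical equal-variance SDT model, one group, E target emotions.
//
//   hits_{ie} ~ Binomial(n_signal_{ie}, Phi(d_{ie}/2 - c_i))
//   fa_i      ~ Binomial(n_noise_i,     Phi(-dbar_i/2 - c_i))
//   d_{ie} ~ Normal(Md_e, Sd_e);  c_i ~ Normal(Mc, Sc)
//   Md_e, Mc ~ Normal(0, 2);  Sd_e, Sc ~ half-Normal(1)
//
// One criterion per participant, shared across emotions: the target-absent
// trials that generate false alarms are common to both emotions in the
// search design, so the shared noise distribution is governed by the
// participant's average sensitivity dbar_i.
// ---------------------------------------------------------------------------

static inline double lbinom_p(int x, int n, double p) {
  if (p <= 0.0) p = 1e-12;
  if (p >= 1.0) p = 1.0 - 1e-12;
  return x * std::log(p) + (n - x) * std::log1p(-p);
}

// [[Rcpp::export]]
List sdt_hier_chain(IntegerMatrix hits, IntegerMatrix nsig, IntegerVector fa,
                    IntegerVector nnoise, int n_iter, int n_warmup,
                    List prior, List init, int n_thin = 1) {
  int n_part = hits.nrow(), E = hits.ncol();
  NumericMatrix d(clone(as<NumericMatrix>(init["d"])));
  NumericVector c(clone(as<NumericVector>(init["c"])));
  NumericVector Md(clone(as<NumericVector>(init["Md"])));
  NumericVector Sd(clone(as<NumericVector>(init["Sd"])));
  double Mc = init["Mc"], Sc = init["Sc"];
  double pr_m = prior["m_sd"], pr_s = prior["s_scale"];

  std::vector<AdaptScale> sc_d(n_part * E), sc_c(n_part), sc_S(E + 1);

  // cached participant log-likelihood (hits rows + shared fa row)
  std::vector<double> llik(n_part);
  auto part_ll = [&](int i, NumericMatrix &dm, double ci) {
    double dbar = 0.0, ll = 0.0;
    for (int e = 0; e < E; ++e) {
      dbar += dm(i, e) / E;
      ll += lbinom_p(hits(i, e), nsig(i, e),
                     R::pnorm(dm(i, e) / 2.0 - ci, 0, 1, 1, 0));
    }
    ll += lbinom_p(fa[i], nnoise[i], R::pnorm(-dbar / 2.0 - ci, 0, 1, 1, 0));
    return ll;
  };
  for (int i = 0; i < n_part; ++i) llik[i] = part_ll(i, d, c[i]);

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, 2 * E + 2);
  NumericMatrix d_postmean(n_part, E);  // running mean of participant d
  int batch = 0;
  std::vector<AdaptScale> sc_exp(2 * (E + 1));
  for (size_t q = 0; q < sc_exp.size(); ++q) sc_exp[q].ls = std::log(0.1);

  for (int it = 0; it < n_iter; ++it) {
   for (int rep = 0; rep < n_thin; ++rep) {
    for (int i = 0; i < n_part; ++i) {
      // d_{ie} moves
      for (int e = 0; e < E; ++e) {
        AdaptScale &a = sc_d[i * E + e]; a.tries++;
        double cur = d(i, e);
        double p = cur + R::norm_rand() * std::exp(a.ls);
        d(i, e) = p;
        double ll = part_ll(i, d, c[i]);
        double lr = ll - llik[i] +
          R::dnorm(p, Md[e], Sd[e], 1) - R::dnorm(cur, Md[e], Sd[e], 1);
        if (std::log(R::unif_rand()) < lr) { llik[i] = ll; a.acc++; }
        else d(i, e) = cur;
      }
      // c_i move
      {
        AdaptScale &a = sc_c[i]; a.tries++;
        double cur = c[i];
        double p = cur + R::norm_rand() * std::exp(a.ls);
        double ll = part_ll(i, d, p);
        double lr = ll - llik[i] + R::dnorm(p, Mc, Sc, 1) - R::dnorm(cur, Mc, Sc, 1);
        if (std::log(R::unif_rand()) < lr) { c[i] = p; llik[i] = ll; a.acc++; }
      }
    }

    // group means: conjugate Gibbs (plain normal hierarchy)
    for (int e = 0; e < E; ++e) {
      double prec = 1.0 / (pr_m * pr_m), num = 0.0;
      for (int i = 0; i < n_part; ++i) {
        double w = 1.0 / (Sd[e] * Sd[e]);
        prec += w; num += d(i, e) * w;
      }
      Md[e] = num / prec + std::sqrt(1.0 / prec) * R::norm_rand();
    }
    {
      double prec = 1.0 / (pr_m * pr_m), num = 0.0;
      for (int i = 0; i < n_part; ++i) {
        double w = 1.0 / (Sc * Sc);
        prec += w; num += c[i] * w;
      }
      Mc = num / prec + std::sqrt(1.0 / prec) * R::norm_rand();
    }
    // group SDs: log-scale MH with half-Normal prior
    for (int e = 0; e <= E; ++e) {
      AdaptScale &a = sc_S[e]; a.tries++;
      double cur = e < E ? Sd[e] : Sc;
      double p = cur * std::exp(R::norm_rand() * std::exp(a.ls));
      double lr = -0.5 * (p * p - cur * cur) / (pr_s * pr_s) +
                  std::log(p) - std::log(cur);
      double M = e < E ? Md[e] : Mc;
      for (int i = 0; i < n_part; ++i) {
        double th = e < E ? d(i, e) : c[i];
        lr += R::dnorm(th, M, p, 1) - R::dnorm(th, M, cur, 1);
      }
      if (std::log(R::unif_rand()) < lr) { if (e < E) Sd[e] = p; else Sc = p; a.acc++; }
    }
    // independence refresh of the group SDs
    for (int e = 0; e < E; ++e)
      Sd[e] = sd_indep_move(Sd[e], Md[e], &d(0, e), n_part, pr_s, false);
    Sc = sd_indep_move(Sc, Mc, &c[0], n_part, pr_s, false);

    // parameter-expansion moves against the hierarchical funnel:
    // translate (theta_i + dlt, M + dlt) and rescale (S' = aS,
    // theta_i' = M + a(theta_i - M)) each family jointly
    for (int f = 0; f <= E; ++f) {  // f < E: d family per emotion; f == E: c
      // translation
      {
        AdaptScale &a = sc_exp[f]; a.tries++;
        double dlt = R::norm_rand() * std::exp(a.ls);
        double Mcur = f < E ? Md[f] : Mc;
        NumericMatrix dprop(clone(d));
        NumericVector cprop(clone(c));
        if (f < E) for (int i = 0; i < n_part; ++i) dprop(i, f) += dlt;
        else for (int i = 0; i < n_part; ++i) cprop[i] += dlt;
        double lr = -0.5 * ((Mcur + dlt) * (Mcur + dlt) - Mcur * Mcur) / (pr_m * pr_m);
        std::vector<double> newll(n_part);
        for (int i = 0; i < n_part; ++i) {
          newll[i] = part_ll(i, dprop, cprop[i]);
          lr += newll[i] - llik[i];
        }
        if (std::log(R::unif_rand()) < lr) {
          if (f < E) { Md[f] += dlt; for (int i = 0; i < n_part; ++i) d(i, f) = dprop(i, f); }
          else { Mc += dlt; for (int i = 0; i < n_part; ++i) c[i] = cprop[i]; }
          for (int i = 0; i < n_part; ++i) llik[i] = newll[i];
          a.acc++;
        }
      }
      // rescale (10% large steps; see the ex-Gaussian sampler)
      {
        AdaptScale &a = sc_exp[E + 1 + f]; a.tries++;
        double big = R::unif_rand() < 0.1 ? 5.0 : 1.0;
        double eps = R::norm_rand() * std::exp(a.ls) * big;
        double alpha = std::exp(eps);
        double Mcur = f < E ? Md[f] : Mc;
        double Scur = f < E ? Sd[f] : Sc;
        double Sp = Scur * alpha;
        NumericMatrix dprop(clone(d));
        NumericVector cprop(clone(c));
        if (f < E) for (int i = 0; i < n_part; ++i)
          dprop(i, f) = Mcur + alpha * (d(i, f) - Mcur);
        else for (int i = 0; i < n_part; ++i)
          cprop[i] = Mcur + alpha * (c[i] - Mcur);
        double lr = eps - 0.5 * (Sp * Sp - Scur * Scur) / (pr_s * pr_s);
        std::vector<double> newll(n_part);
        for (int i = 0; i < n_part; ++i) {
          newll[i] = part_ll(i, dprop, cprop[i]);
          lr += newll[i] - llik[i];
        }
        if (std::log(R::unif_rand()) < lr) {
          if (f < E) { Sd[f] = Sp; for (int i = 0; i < n_part; ++i) d(i, f) = dprop(i, f); }
          else { Sc = Sp; for (int i = 0; i < n_part; ++i) c[i] = cprop[i]; }
          for (int i = 0; i < n_part; ++i) llik[i] = newll[i];
          a.acc++;
        }
      }
    }
   }  // n_thin sweeps

    if (it < n_warmup && (it + 1) % 25 == 0) {
      ++batch;
      for (size_t q = 0; q < sc_d.size(); ++q) adapt(sc_d[q], batch);
      for (size_t q = 0; q < sc_c.size(); ++q) adapt(sc_c[q], batch);
      for (size_t q = 0; q < sc_S.size(); ++q) adapt(sc_S[q], batch);
      for (size_t q = 0; q < sc_exp.size(); ++q) adapt(sc_exp[q], batch);
    }

    if (it >= n_warmup) {
      int r = it - n_warmup;
      for (int e = 0; e < E; ++e) { draws(r, e) = Md[e]; draws(r, E + e) = Sd[e]; }
      draws(r, 2 * E) = Mc;
      draws(r, 2 * E + 1) = Sc;
      for (int i = 0; i < n_part; ++i)
        for (int e = 0; e < E; ++e)
          d_postmean(i, e) += d(i, e) / n_keep;
    }
  }
  return List::create(_["draws"] = draws, _["d_postmean"] = d_postmean);
}
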