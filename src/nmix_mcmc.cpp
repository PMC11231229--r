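// Compiled kernels for the binomial N-mixture sampler and the pointwise
// log-likelihood assembly consumed by the model-selection criteria.
//
// Layout conventions (fixed across the package):
//   units  u = i + t*S          (site i, season t, both 0-based; U = S*T)
//   obs    o = u + j*U          (visit j, 0-based; column-major over units)
//   y      integer matrix U x J
//   Xa     S x nb        abundance design (first/only season)
//   Xg     S*(T-1) x ng  growth design, row i + (t-2)*S for season t >= 2
//   Xd     U*J x na      detection design in obs order
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// lgamma(k+1) lookup, grown on demand; N stays in the low hundreds for
// realistic point-count abundances so the table is tiny.
struct LFact {
  std::vector<double> t;
  LFact() { t.reserve(512); t.push_back(0.0); }
  inline double operator()(int k) {
    while ((int)t.size() <= k) t.push_back(t.back() + std::log((double)t.size()));
    return t[k];
  }
};

// log(p) and log(1-p) of the inverse logit, stable for |eta| up to ~700.
static inline void logit_logprobs(double eta, double &logp, double &log1mp) {
  if (eta > 0) {
    logp = -std::log1p(std::exp(-eta));
    log1mp = logp - eta;
  } else {
    log1mp = -std::log1p(std::exp(eta));
    logp = log1mp + eta;
  }
}

// expected abundance per unit under the log link plus, for multi-season
// models, the multiplicative growth recursion mu[i,t] = psi[i,t]*mu[i,t-1].
static void compute_logmu(const NumericMatrix &Xa, const NumericMatrix &Xg,
                          const double *beta, const double *delta,
                          int S, int T, std::vector<double> &logmu) {
  const int nb = Xa.ncol();
  for (int i = 0; i < S; i++) {
    double eta = 0.0;
    for (int k = 0; k < nb; k++) eta += Xa(i, k) * beta[k];
    logmu[i] = eta;
  }
  if (T > 1) {
    const int ng = Xg.ncol();
    for (int t = 1; t < T; t++) {
      for (int i = 0; i < S; i++) {
        const int r = i + (t - 1) * S;
        double lpsi = 0.0;
        for (int k = 0; k < ng; k++) lpsi += Xg(r, k) * delta[k];
        logmu[i + t * S] = logmu[i + (t - 1) * S] + lpsi;
      }
    }
  }
}

static inline double log_prior(const double *x, int n, double sd) {
  double s = 0.0;
  for (int k = 0; k < n; k++) s += x[k] * x[k];
  return -0.5 * s / (sd * sd);
}

// sum over visits of log Binomial(y[u,j]; N, p[u,j]) from cached log-probs
static inline double unit_binom_ll(const IntegerMatrix &y, const double *logp,
                                   const double *log1mp, int U, int J, int u,
                                   int N, LFact &lf) {
  double s = 0.0;
  for (int j = 0; j < J; j++) {
    const int o = u + j * U;
    const int yy = y(u, j);
    s += lf(N) - lf(yy) - lf(N - yy) + yy * logp[o] + (N - yy) * log1mp[o];
  }
  return s;
}

static void detection_logprobs(const NumericMatrix &Xd, const double *alpha,
                               std::vector<double> &logp,
                               std::vector<double> &log1mp) {
  const int n_obs = Xd.nrow(), na = Xd.ncol();
  for (int o = 0; o < n_obs; o++) {
    double eta = 0.0;
    for (int k = 0; k < na; k++) eta += Xd(o, k) * alpha[k];
    logit_logprobs(eta, logp[o], log1mp[o]);
  }
}

// Cholesky factor of a small symmetric matrix (row-major d x d); returns
// false if not positive definite.
static bool small_cholesky(const std::vector<double> &A, int d,
                           std::vector<double> &L) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; i++) {
    for (int j = 0; j <= i; j++) {
      double s = A[i * d + j];
      for (int k = 0; k < j; k++) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

// Running mean/covariance of a coefficient block, used to shape burn-in
// proposal covariances (Haario-style adaptation, frozen before retention).
struct BlockAdapt {
  int d = 0;
  long n = 0;
  std::vector<double> mean, C, L;  // C, L row-major d x d
  void init(int dim, double init_scale) {
    d = dim;
    n = 0;
    mean.assign(d, 0.0);
    C.assign(d * d, 0.0);
    L.assign(d * d, 0.0);
    for (int i = 0; i < d; i++) L[i * d + i] = init_scale;
  }
  void observe(const double *x) {
    n++;
    for (int i = 0; i < d; i++) {
      const double di = x[i] - mean[i];
      mean[i] += di / (double)n;
      for (int j = 0; j <= i; j++)
        C[i * d + j] += di * (x[j] - mean[j]);
    }
  }
  // refresh L from the current accumulation window, then restart the
  // window so early-transient drift does not inflate later proposals
  bool refresh() {
    if (n < std::max(50L, 10L * d)) return false;
    std::vector<double> A(d * d);
    for (int i = 0; i < d; i++)
      for (int j = 0; j <= i; j++) {
        double c = C[i * d + j] / (double)(n - 1);
        if (i == j) c += 1e-8;
        A[i * d + j] = A[j * d + i] = c;
      }
    std::vector<double> Lt;
    bool ok = small_cholesky(A, d, Lt);
    if (ok) L = Lt;
    n = 0;
    std::fill(mean.begin(), mean.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    return ok;
  }
  void propose(const double *x, double s, double *out) const {
    // out = x + s * L z
    std::vector<double> z(d);
    for (int i = 0; i < d; i++) z[i] = norm_rand();
    for (int i = 0; i < d; i++) {
      double inc = 0.0;
      for (int j = 0; j <= i; j++) inc += L[i * d + j] * z[j];
      out[i] = x[i] + s * inc;
    }
  }
};

// One MCMC chain: sitewise integer random-walk Metropolis on the latent
// abundances (per-unit half-widths adapted during burn-in), one Gaussian
// random-walk Metropolis block for the abundance-side coefficients (beta
// and, seasonal, delta together — they jointly determine mu so they move as
// one block) against the Poisson likelihood of the latent N, and one block
// for the detection coefficients against the binomial likelihood. Proposal
// scales, covariances and half-widths adapt during burn-in only and are
// frozen before the first retained iteration, so retained draws come from a
// fixed Metropolis kernel.
// [[Rcpp::export]]
List nmix_chain_cpp(IntegerMatrix y, NumericMatrix Xa, NumericMatrix Xg,
                    NumericMatrix Xd, int n_sites, int n_seasons, int n_iter,
                    double burn_frac, int thin, NumericVector init_beta,
                    NumericVector init_alpha, NumericVector init_delta,
                    IntegerVector init_N, double prior_sd, double scale_beta,
                    double scale_alpha, double scale_delta,
                    int latent_halfwidth, bool adapt, bool update_coefs,
                    int latent_gibbs_interval) {
  const int S = n_sites, T = n_seasons, U = y.nrow(), J = y.ncol();
  const int n_obs = U * J;
  const int nb = init_beta.size(), na = init_alpha.size(),
            nd = init_delta.size();
  const bool seasonal = (T > 1) && nd > 0;
  const int nc = nb + (seasonal ? nd : 0);  // combined abundance block
  LFact lf;
  const int *yp = INTEGER(y);              // column-major: y[u + j*U]
  const double *xd = REAL(Xd);             // column-major: xd[o + k*n_obs]

  std::vector<double> coef(nc);  // beta then delta
  for (int k = 0; k < nb; k++) coef[k] = init_beta[k];
  if (seasonal) for (int k = 0; k < nd; k++) coef[nb + k] = init_delta[k];
  std::vector<double> alpha(init_alpha.begin(), init_alpha.end());
  std::vector<int> N(init_N.begin(), init_N.end());

  std::vector<int> maxy(U, 0);
  int topN = 0;
  for (int u = 0; u < U; u++) {
    int m = 0;
    for (int j = 0; j < J; j++) m = std::max(m, yp[u + j * U]);
    maxy[u] = m;
    if (N[u] < m) stop("initial latent abundance below the maximum count");
    topN = std::max(topN, N[u]);
  }

  std::vector<double> logmu(U), mu(U), logp(n_obs), log1mp(n_obs);
  std::vector<double> s1mp(U, 0.0);  // per-unit sum over visits of log(1-p)
  compute_logmu(Xa, Xg, coef.data(), coef.data() + nb, S, T, logmu);
  detection_logprobs(Xd, alpha.data(), logp, log1mp);
  for (int u = 0; u < U; u++) {
    if (!std::isfinite(logmu[u]))
      stop("non-finite abundance mean at initialization");
    mu[u] = std::exp(logmu[u]);
    double s = 0.0;
    for (int j = 0; j < J; j++) s += log1mp[u + j * U];
    s1mp[u] = s;
  }

  // sufficient statistic for the detection block: sum_o y_o * x_o
  std::vector<double> yX(na, 0.0);
  for (int k = 0; k < na; k++) {
    double s = 0.0;
    for (int o = 0; o < n_obs; o++) s += yp[o] * xd[o + k * n_obs];
    yX[k] = s;
  }
  std::vector<double> eta(n_obs), eta_prop(n_obs);
  for (int o = 0; o < n_obs; o++) {
    double e = 0.0;
    for (int k = 0; k < na; k++) e += xd[o + k * n_obs] * alpha[k];
    eta[o] = e;
  }

  const int n_burn = (int)std::floor(n_iter * burn_frac);
  const int n_ret = (n_iter - n_burn) / thin;
  IntegerMatrix out_N(n_ret, U);
  NumericMatrix out_beta(n_ret, nb), out_alpha(n_ret, na), out_delta(n_ret, nd);

  std::vector<double> logmu_prop(U), mu_prop(U), log1mp_prop(n_obs);
  std::vector<double> cprop(std::max(nc, na)), gibbs_buf;

  BlockAdapt ad_coef, ad_alpha;
  ad_coef.init(nc, 1.0);
  ad_alpha.init(na, 1.0);
  double s_coef = scale_beta, s_alpha = scale_alpha;
  bool coef_shaped = false, alpha_shaped = false;
  (void)scale_delta;  // the combined block uses one scalar scale

  // per-unit latent half-widths, adapted from the burn-in sd of N
  std::vector<int> hw(U, latent_halfwidth);
  std::vector<double> n_mean(U, 0.0), n_M2(U, 0.0);
  long n_obs_adapt = 0;

  // acceptance bookkeeping: [0] latent, [1] abundance block, [2] detection
  long acc_post[3] = {0, 0, 0}, try_post[3] = {0, 0, 0};
  long acc_batch[3] = {0, 0, 0}, try_batch[3] = {0, 0, 0};
  const int batch = 50, checkpoint = 250;

  int row = 0;
  for (int it = 1; it <= n_iter; it++) {
    const bool post = it > n_burn;

    // --- latent abundances ---------------------------------------------
    lf(topN + 256);  // direct table pointer safe for any in-range proposal
    const double *lg = lf.t.data();
    for (int u = 0; u < U; u++) {
      const int du = hw[u];
      int d = (int)(unif_rand() * (2 * du));
      if (d >= 2 * du) d = 2 * du - 1;
      d = (d < du) ? d - du : d - du + 1;
      const int Nu = N[u], Np = Nu + d;
      if (post) try_post[0]++; else try_batch[0]++;
      if (Np < maxy[u]) continue;  // outside the support: reject outright
      if (Np >= (int)lf.t.size()) { lf(Np + 256); lg = lf.t.data(); }
      double lr = (Np - Nu) * (logmu[u] + s1mp[u]) +
                  (J - 1) * (lg[Np] - lg[Nu]);
      for (int j = 0; j < J; j++) {
        const int yy = yp[u + j * U];
        lr -= lg[Np - yy] - lg[Nu - yy];
      }
      if (lr >= 0.0 || std::log(unif_rand()) < lr) {
        N[u] = Np;
        if (Np > topN) topN = Np;
        if (post) acc_post[0]++; else acc_batch[0]++;
      }
    }

    // --- periodic exact refresh of N from its full conditional ----------
    // The conditional pmf of N_u given coefficients is supported on
    // N >= max_j y_uj with an upper tail dominated by a Poisson of rate
    // mu_u * prod_j (1 - p_uj); enumerating it is cheap and decorrelates
    // the latent states from the abundance/detection ridge far faster than
    // the local random walk alone.
    if (latent_gibbs_interval > 0 && it % latent_gibbs_interval == 0) {
      for (int u = 0; u < U; u++) {
        const double thinned = std::exp(logmu[u] + s1mp[u]);
        const int lo = maxy[u];
        // upper tail bounded by a Poisson of rate `thinned`; 12 sd + 15 puts
        // the omitted mass far below 1e-12
        int hi = lo + 15 + (int)(thinned + 12.0 * std::sqrt(thinned + 1.0));
        if (hi >= (int)lf.t.size()) { lf(hi + 256); lg = lf.t.data(); }
        const double drift = logmu[u] + s1mp[u];
        double gmax = R_NegInf;
        gibbs_buf.assign(hi - lo + 1, 0.0);
        std::vector<double> &g = gibbs_buf;
        for (int Nv = lo; Nv <= hi; Nv++) {
          double gv = (J - 1) * lg[Nv] + Nv * drift;
          for (int j = 0; j < J; j++) gv -= lg[Nv - yp[u + j * U]];
          g[Nv - lo] = gv;
          if (gv > gmax) gmax = gv;
        }
        double tot = 0.0;
        for (size_t k = 0; k < g.size(); k++) {
          g[k] = std::exp(g[k] - gmax);
          tot += g[k];
        }
        const double target = unif_rand() * tot;
        double cum = 0.0;
        int pick = hi;
        for (size_t k = 0; k < g.size(); k++) {
          cum += g[k];
          if (cum >= target) { pick = lo + (int)k; break; }
        }
        N[u] = pick;
        if (pick > topN) topN = pick;
      }
    }

    if (update_coefs) {
      // --- abundance block: beta (+ delta), Poisson likelihood ---------
      {
        ad_coef.propose(coef.data(), s_coef, cprop.data());
        compute_logmu(Xa, Xg, cprop.data(), cprop.data() + nb, S, T,
                      logmu_prop);
        double lr = log_prior(cprop.data(), nc, prior_sd) -
                    log_prior(coef.data(), nc, prior_sd);
        bool ok = true;
        for (int u = 0; u < U; u++) {
          mu_prop[u] = std::exp(logmu_prop[u]);
          if (!std::isfinite(mu_prop[u])) { ok = false; break; }
          lr += N[u] * (logmu_prop[u] - logmu[u]) - (mu_prop[u] - mu[u]);
        }
        if (post) try_post[1]++; else try_batch[1]++;
        if (ok && (lr >= 0.0 || std::log(unif_rand()) < lr)) {
          std::copy(cprop.begin(), cprop.begin() + nc, coef.begin());
          std::swap(logmu, logmu_prop);
          std::swap(mu, mu_prop);
          if (post) acc_post[1]++; else acc_batch[1]++;
        }
      }
      // --- detection block: alpha, binomial likelihood -----------------
      {
        ad_alpha.propose(alpha.data(), s_alpha, cprop.data());
        double lr = log_prior(cprop.data(), na, prior_sd) -
                    log_prior(alpha.data(), na, prior_sd);
        for (int k = 0; k < na; k++) lr += yX[k] * (cprop[k] - alpha[k]);
        for (int o = 0; o < n_obs; o++) {
          double e = 0.0;
          for (int k = 0; k < na; k++) e += xd[o + k * n_obs] * cprop[k];
          eta_prop[o] = e;
          const double l1m =
              (e > 0) ? -e - std::log1p(std::exp(-e)) : -std::log1p(std::exp(e));
          log1mp_prop[o] = l1m;
          lr += N[o % U] * (l1m - log1mp[o]);
        }
        if (post) try_post[2]++; else try_batch[2]++;
        if (lr >= 0.0 || std::log(unif_rand()) < lr) {
          std::copy(cprop.begin(), cprop.begin() + na, alpha.begin());
          std::swap(log1mp, log1mp_prop);
          std::swap(eta, eta_prop);
          for (int u = 0; u < U; u++) {
            double s = 0.0;
            for (int j = 0; j < J; j++) s += log1mp[u + j * U];
            s1mp[u] = s;
          }
          if (post) acc_post[2]++; else acc_batch[2]++;
        }
      }
    }

    // --- burn-in adaptation, frozen at the first retained iteration -----
    if (adapt && !post) {
      if (update_coefs) {
        ad_coef.observe(coef.data());
        ad_alpha.observe(alpha.data());
      }
      n_obs_adapt++;
      for (int u = 0; u < U; u++) {
        const double d0 = N[u] - n_mean[u];
        n_mean[u] += d0 / (double)n_obs_adapt;
        n_M2[u] += d0 * (N[u] - n_mean[u]);
      }
      if (it % batch == 0) {
        for (int b = 1; b <= 2; b++) {
          if (try_batch[b] == 0) continue;
          const double rate = (double)acc_batch[b] / (double)try_batch[b];
          double *s = (b == 1) ? &s_coef : &s_alpha;
          *s *= std::exp(rate - 0.3);
          *s = std::min(std::max(*s, 1e-4), 50.0);
          acc_batch[b] = 0;
          try_batch[b] = 0;
        }
        acc_batch[0] = 0;
        try_batch[0] = 0;
      }
      if (it % checkpoint == 0) {
        if (update_coefs) {
          // on the first successful covariance refresh, restart the scalar
          // at the optimal-scaling value for a shaped Gaussian proposal;
          // afterwards only the acceptance-rate batches move it
          if (ad_coef.refresh() && !coef_shaped) {
            s_coef = 2.38 / std::sqrt((double)nc);
            coef_shaped = true;
          }
          if (ad_alpha.refresh() && !alpha_shaped) {
            s_alpha = 2.38 / std::sqrt((double)na);
            alpha_shaped = true;
          }
        }
        if (n_obs_adapt > 20) {
          for (int u = 0; u < U; u++) {
            const double sd =
                std::sqrt(n_M2[u] / (double)(n_obs_adapt - 1));
            hw[u] = std::max(1, std::min(200, (int)std::ceil(1.2 * sd)));
          }
        }
      }
    }

    if (post && (it - n_burn) % thin == 0) {
      for (int u = 0; u < U; u++) out_N(row, u) = N[u];
      for (int k = 0; k < nb; k++) out_beta(row, k) = coef[k];
      for (int k = 0; k < na; k++) out_alpha(row, k) = alpha[k];
      for (int k = 0; k < nd; k++)
        out_delta(row, k) = seasonal ? coef[nb + k] : init_delta[k];
      row++;
    }
  }

  NumericVector acc(4);
  acc[0] = try_post[0] > 0 ? (double)acc_post[0] / (double)try_post[0] : NA_REAL;
  acc[1] = try_post[1] > 0 ? (double)acc_post[1] / (double)try_post[1] : NA_REAL;
  acc[2] = try_post[2] > 0 ? (double)acc_post[2] / (double)try_post[2] : NA_REAL;
  acc[3] = seasonal ? acc[1] : NA_REAL;  // delta moves with the beta block
  acc.names() = CharacterVector::create("latent", "beta", "alpha", "delta");
  return List::create(_["N"] = out_N, _["beta"] = out_beta,
                      _["alpha"] = out_alpha, _["delta"] = out_delta,
                      _["acceptance"] = acc,
                      _["scales"] = NumericVector::create(
                          _["coef"] = s_coef, _["alpha"] = s_alpha));
}

// Conditional (observation-level) pointwise log-likelihood matrix:
// entry (s, o) = log Binomial(y_o; N_u^{(s)}, p_o^{(s)}).
// [[Rcpp::export]]
NumericMatrix cond_loglik_cpp(IntegerMatrix Ndraws, NumericMatrix alpha_draws,
                              IntegerMatrix y, NumericMatrix Xd) {
  const int ndr = Ndraws.nrow(), U = y.nrow(), J = y.ncol(), n_obs = U * J;
  LFact lf;
  std::vector<double> logp(n_obs), log1mp(n_obs), arow(alpha_draws.ncol());
  NumericMatrix out(ndr, n_obs);
  for (int s = 0; s < ndr; s++) {
    for (int k = 0; k < alpha_draws.ncol(); k++) arow[k] = alpha_draws(s, k);
    detection_logprobs(Xd, arow.data(), logp, log1mp);
    for (int o = 0; o < n_obs; o++) {
      const int u = o % U, yy = y(u, o / U), N = Ndraws(s, u);
      out(s, o) = lf(N) - lf(yy) - lf(N - yy) + yy * logp[o] +
                  (N - yy) * log1mp[o];
    }
  }
  return out;
}

// Joint pointwise log-likelihood matrix, one column per unit (site or
// site-season): binomial terms over visits plus the Poisson state term.
// [[Rcpp::export]]
NumericMatrix joint_loglik_cpp(IntegerMatrix Ndraws, NumericMatrix beta_draws,
                               NumericMatrix alpha_draws,
                               NumericMatrix delta_draws, IntegerMatrix y,
                               NumericMatrix Xa, NumericMatrix Xg,
                               NumericMatrix Xd, int n_sites, int n_seasons) {
  const int ndr = Ndraws.nrow(), U = y.nrow(), J = y.ncol(), n_obs = U * J;
  const int S = n_sites, T = n_seasons;
  LFact lf;
  std::vector<double> logp(n_obs), log1mp(n_obs), logmu(U);
  std::vector<double> arow(alpha_draws.ncol()), brow(beta_draws.ncol()),
      drow(std::max(1, (int)delta_draws.ncol()));
  NumericMatrix out(ndr, U);
  for (int s = 0; s < ndr; s++) {
    for (int k = 0; k < alpha_draws.ncol(); k++) arow[k] = alpha_draws(s, k);
    for (int k = 0; k < beta_draws.ncol(); k++) brow[k] = beta_draws(s, k);
    for (int k = 0; k < delta_draws.ncol(); k++) drow[k] = delta_draws(s, k);
    detection_logprobs(Xd, arow.data(), logp, log1mp);
    compute_logmu(Xa, Xg, brow.data(), drow.data(), S, T, logmu);
    for (int u = 0; u < U; u++) {
      const int N = Ndraws(s, u);
      out(s, u) = unit_binom_ll(y, logp.data(), log1mp.data(), U, J, u, N, lf) +
                  N * logmu[u] - std::exp(logmu[u]) - lf(N);
    }
  }
  return out;
}

// Posterior-predictive replicate counts, one row per retained draw; RNG is
// consumed draw-major then observation-major (the streaming scorer below
// uses the identical order).
// [[Rcpp::export]]
IntegerMatrix pp_replicates_cpp(IntegerMatrix Ndraws, NumericMatrix alpha_draws,
                                IntegerMatrix y, NumericMatrix Xd) {
  const int ndr = Ndraws.nrow(), U = y.nrow(), J = y.ncol(), n_obs = U * J;
  std::vector<double> logp(n_obs), log1mp(n_obs), arow(alpha_draws.ncol());
  IntegerMatrix out(ndr, n_obs);
  for (int s = 0; s < ndr; s++) {
    for (int k = 0; k < alpha_draws.ncol(); k++) arow[k] = alpha_draws(s, k);
    detection_logprobs(Xd, arow.data(), logp, log1mp);
    for (int o = 0; o < n_obs; o++) {
      const int u = o % U;
      out(s, o) = (int)R::rbinom((double)Ndraws(s, u), std::exp(logp[o]));
    }
  }
  return out;
}

struct StreamStats {
  // per-element running log-sum-exp and Welford variance accumulators
  std::vector<double> m, se, mean, M2;
  long n = 0;
  void init(int k) {
    m.assign(k, R_NegInf);
    se.assign(k, 0.0);
    mean.assign(k, 0.0);
    M2.assign(k, 0.0);
  }
  inline void add(int i, double x) {
    if (x <= m[i]) {
      se[i] += std::exp(x - m[i]);
    } else {
      se[i] = se[i] * std::exp(m[i] - x) + 1.0;
      m[i] = x;
    }
    const double d = x - mean[i];
    mean[i] += d / (double)n;
    M2[i] += d * (x - mean[i]);
  }
  NumericVector lpd() const {
    NumericVector out(m.size());
    for (size_t i = 0; i < m.size(); i++)
      out[i] = m[i] + std::log(se[i] / (double)n);
    return out;
  }
  NumericVector var() const {
    NumericVector out(m.size());
    for (size_t i = 0; i < m.size(); i++) out[i] = M2[i] / (double)(n - 1);
    return out;
  }
};

// Single streaming pass over the retained draws producing every summary the
// three criteria need, without materializing draws-by-observation matrices.
// pp_stride > 1 thins the draws used for posterior-predictive replicates.
// [[Rcpp::export]]
List pointwise_streams_cpp(IntegerMatrix Ndraws, NumericMatrix beta_draws,
                           NumericMatrix alpha_draws, NumericMatrix delta_draws,
                           IntegerMatrix y, NumericMatrix Xa, NumericMatrix Xg,
                           NumericMatrix Xd, int n_sites, int n_seasons,
                           int pp_stride) {
  const int ndr = Ndraws.nrow(), U = y.nrow(), J = y.ncol(), n_obs = U * J;
  const int S = n_sites, T = n_seasons;
  LFact lf;
  std::vector<double> logp(n_obs), log1mp(n_obs), logmu(U);
  std::vector<double> arow(alpha_draws.ncol()), brow(beta_draws.ncol()),
      drow(std::max(1, (int)delta_draws.ncol()));
  StreamStats cond, joint;
  cond.init(n_obs);
  joint.init(U);
  std::vector<double> pp_mean(n_obs, 0.0), pp_M2(n_obs, 0.0);
  long pp_n = 0;

  for (int s = 0; s < ndr; s++) {
    for (int k = 0; k < alpha_draws.ncol(); k++) arow[k] = alpha_draws(s, k);
    for (int k = 0; k < beta_draws.ncol(); k++) brow[k] = beta_draws(s, k);
    for (int k = 0; k < delta_draws.ncol(); k++) drow[k] = delta_draws(s, k);
    detection_logprobs(Xd, arow.data(), logp, log1mp);
    compute_logmu(Xa, Xg, brow.data(), drow.data(), S, T, logmu);

    cond.n++;
    joint.n++;
    for (int u = 0; u < U; u++) {
      const int N = Ndraws(s, u);
      double jsum = N * logmu[u] - std::exp(logmu[u]) - lf(N);
      for (int j = 0; j < J; j++) {
        const int o = u + j * U, yy = y(u, j);
        const double ll = lf(N) - lf(yy) - lf(N - yy) + yy * logp[o] +
                          (N - yy) * log1mp[o];
        cond.add(o, ll);
        jsum += ll;
      }
      joint.add(u, jsum);
    }
    if (s % pp_stride == 0) {
      pp_n++;
      for (int o = 0; o < n_obs; o++) {
        const int u = o % U;
        const double yr =
            R::rbinom((double)Ndraws(s, u), std::exp(logp[o]));
        const double d = yr - pp_mean[o];
        pp_mean[o] += d / (double)pp_n;
        pp_M2[o] += d * (yr - pp_mean[o]);
      }
    }
  }

  NumericVector pmu(n_obs), pvar(n_obs);
  for (int o = 0; o < n_obs; o++) {
    pmu[o] = pp_mean[o];
    pvar[o] = pp_n > 1 ? pp_M2[o] / (double)(pp_n - 1) : NA_REAL;
  }
  return List::create(
      _["cond_lpd"] = cond.lpd(), _["cond_var"] = cond.var(),
      _["joint_lpd"] = joint.lpd(), _["joint_var"] = joint.var(),
      _["pp_mean"] = pmu, _["pp_var"] = pvar, _["n_draws"] = (double)ndr,
      _["pp_draws"] = (double)pp_n);
}

// Column-wise log-mean-exp (log predictive density) and sample variance of a
// pointwise log-likelihood matrix, draws in rows.
// [[Rcpp::export]]
List col_lpd_var_cpp(NumericMatrix ll) {
  const int ndr = ll.nrow(), k = ll.ncol();
  StreamStats st;
  st.init(k);
  for (int s = 0; s < ndr; s++) {
    st.n++;
    for (int i = 0; i < k; i++) st.add(i, ll(s, i));
  }
  return List::create(_["lpd"] = st.lpd(), _["var"] = st.var());
}
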