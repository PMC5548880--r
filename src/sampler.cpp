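// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// hazard-ratio network meta-analysis model.
//
// State layout (flattened, in this order):
//   d[0..n_d)        basic contrasts (one per non-reference regimen x endpoint)
//   delta[0..N)      study-specific effects, one per estimate row
//   s2[0..N)         within-study variances, one per estimate row
//   tau[0..n_ep)     between-study SDs per endpoint
//   rho              shared within-study correlation
//
// tau and rho are updated on logit-transformed unconstrained scales with the
// appropriate Jacobian terms; s2 on the log scale. Step sizes adapt toward a
// target acceptance rate during burn-in only, so the sampling phase is a
// fixed-kernel Markov chain.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// log N(x; mu, sd)
static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// log InverseGamma(x; a, b) density
static inline double dinvgamma_log(double x, double a, double b) {
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(x) - b / x;
}

struct ModelData {
  int N, n_d, n_ep, n_study;
  std::vector<double> y, alpha, beta;
  std::vector<int> study, ep, ia, ib; // ia/ib: -1 means reference
  std::vector<std::vector<int>> study_rows;      // estimates per study
  std::vector<std::vector<int>> d_adj;           // estimate rows touching d_j
  std::vector<std::vector<int>> d_sign;          // +1 via ib, -1 via ia
  std::vector<std::vector<int>> ep_rows;         // estimate rows per endpoint
  double tau_upper, effect_sd, rho_lo, rho_hi;
};

struct State {
  std::vector<double> d, delta, s2;
  std::vector<double> tau;
  double rho;
  double u_rho;                  // logit-scale rho
  std::vector<double> u_tau;     // logit-scale tau
};

static inline double contrast_mean(const ModelData& M, const State& S, int i) {
  double db = (M.ib[i] >= 0) ? S.d[M.ib[i]] : 0.0;
  double da = (M.ia[i] >= 0) ? S.d[M.ia[i]] : 0.0;
  return db - da;
}

// log density of the study's observation block: residuals y - delta,
// compound-symmetry covariance with variances s2 and correlation rho.
static double obs_block(const ModelData& M, const State& S, int s) {
  const std::vector<int>& rows = M.study_rows[s];
  int m = (int)rows.size();
  double sz = 0.0, szz = 0.0, slog = 0.0;
  for (int k = 0; k < m; ++k) {
    int i = rows[k];
    double z = (M.y[i] - S.delta[i]) / std::sqrt(S.s2[i]);
    sz += z; szz += z * z; slog += std::log(S.s2[i]);
  }
  double rho = S.rho;
  double logdet = slog + (m - 1) * std::log1p(-rho) + std::log1p((m - 1) * rho);
  double quad = (szz - rho / (1.0 + (m - 1) * rho) * sz * sz) / (1.0 - rho);
  return -0.5 * (m * 1.8378770664093453 + logdet + quad);
}

static inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// [[Rcpp::export]]
double nma_lp_cpp(NumericVector y, IntegerVector study, IntegerVector ep,
                  IntegerVector ia, IntegerVector ib,
                  NumericVector alpha, NumericVector beta,
                  NumericVector d, NumericVector delta, NumericVector s2,
                  NumericVector tau, double rho,
                  double tau_upper, double effect_sd,
                  double rho_lo, double rho_hi) {
  int N = y.size();
  for (int i = 0; i < N; ++i) if (s2[i] <= 0) return R_NegInf;
  for (int e = 0; e < tau.size(); ++e)
    if (tau[e] <= 0 || tau[e] >= tau_upper) return R_NegInf;
  if (rho < rho_lo || rho > rho_hi) return R_NegInf;

  ModelData M;
  M.N = N;
  M.y = as<std::vector<double>>(y);
  M.study = as<std::vector<int>>(study);
  M.ia = as<std::vector<int>>(ia);
  M.ib = as<std::vector<int>>(ib);
  int n_study = 0;
  for (int i = 0; i < N; ++i) n_study = std::max(n_study, M.study[i] + 1);
  M.study_rows.assign(n_study, {});
  for (int i = 0; i < N; ++i) M.study_rows[M.study[i]].push_back(i);

  State S;
  S.d = as<std::vector<double>>(d);
  S.delta = as<std::vector<double>>(delta);
  S.s2 = as<std::vector<double>>(s2);
  S.rho = rho;

  double lp = 0.0;
  for (int s = 0; s < n_study; ++s) lp += obs_block(M, S, s);
  for (int i = 0; i < N; ++i)
    lp += dnorm_log(S.delta[i], contrast_mean(M, S, i), tau[ep[i]]);
  for (int j = 0; j < d.size(); ++j) lp += dnorm_log(d[j], 0.0, effect_sd);
  for (int i = 0; i < N; ++i) lp += dinvgamma_log(S.s2[i], alpha[i], beta[i]);
  lp -= tau.size() * std::log(tau_upper);
  lp -= std::log(rho_hi - rho_lo);
  return lp;
}

// [[Rcpp::export]]
List nma_sample_chain(NumericVector y, IntegerVector study, IntegerVector ep,
                      IntegerVector ia, IntegerVector ib,
                      NumericVector alpha, NumericVector beta,
                      int n_d, int n_ep,
                      double tau_upper, double effect_sd,
                      double rho_lo, double rho_hi,
                      NumericVector d_init, NumericVector delta_init,
                      NumericVector s2_init, NumericVector tau_init,
                      double rho_init,
                      int n_burnin, int n_samples,
                      int adapt_interval, double target_accept) {
  ModelData M;
  M.N = y.size(); M.n_d = n_d; M.n_ep = n_ep;
  M.y = as<std::vector<double>>(y);
  M.alpha = as<std::vector<double>>(alpha);
  M.beta = as<std::vector<double>>(beta);
  M.study = as<std::vector<int>>(study);
  M.ep = as<std::vector<int>>(ep);
  M.ia = as<std::vector<int>>(ia);
  M.ib = as<std::vector<int>>(ib);
  M.tau_upper = tau_upper; M.effect_sd = effect_sd;
  M.rho_lo = rho_lo; M.rho_hi = rho_hi;

  M.n_study = 0;
  for (int i = 0; i < M.N; ++i) M.n_study = std::max(M.n_study, M.study[i] + 1);
  M.study_rows.assign(M.n_study, {});
  for (int i = 0; i < M.N; ++i) M.study_rows[M.study[i]].push_back(i);
  M.d_adj.assign(n_d, {});
  M.d_sign.assign(n_d, {});
  for (int i = 0; i < M.N; ++i) {
    if (M.ib[i] >= 0) {
      M.d_adj[M.ib[i]].push_back(i);
      M.d_sign[M.ib[i]].push_back(1);
    }
    if (M.ia[i] >= 0 && M.ia[i] != M.ib[i]) {
      M.d_adj[M.ia[i]].push_back(i);
      M.d_sign[M.ia[i]].push_back(-1);
    }
  }
  M.ep_rows.assign(n_ep, {});
  for (int i = 0; i < M.N; ++i) M.ep_rows[M.ep[i]].push_back(i);

  State S;
  S.d = as<std::vector<double>>(d_init);
  S.delta = as<std::vector<double>>(delta_init);
  S.s2 = as<std::vector<double>>(s2_init);
  S.tau = as<std::vector<double>>(tau_init);
  S.rho = rho_init;
  S.u_tau.resize(n_ep);
  for (int e = 0; e < n_ep; ++e) {
    double p = S.tau[e] / tau_upper;
    S.u_tau[e] = std::log(p / (1.0 - p));
  }
  {
    double p = (S.rho - rho_lo) / (rho_hi - rho_lo);
    S.u_rho = std::log(p / (1.0 - p));
  }

  // parameter bookkeeping: n_d + N (delta) + N (s2) + n_ep (tau) + 1 (rho),
  // plus n_d joint translation moves (d_j and its study effects together)
  // which decorrelate d from delta when the heterogeneity is small
  int P = n_d + 2 * M.N + n_ep + 1;
  int P_all = P + n_d;
  std::vector<double> lstep(P_all);
  for (int j = 0; j < n_d; ++j) lstep[P + j] = std::log(0.3);
  for (int j = 0; j < n_d; ++j) lstep[j] = std::log(0.3);
  for (int i = 0; i < M.N; ++i) {
    double v = S.s2[i];
    double t0 = S.tau[M.ep[i]];
    double sd0 = std::sqrt(1.0 / (1.0 / v + 1.0 / (t0 * t0)));
    lstep[n_d + i] = std::log(2.4 * sd0);
    lstep[n_d + M.N + i] =
      std::log(std::min(1.0, 2.4 / std::sqrt(M.alpha[i] + 1.0)));
  }
  for (int e = 0; e < n_ep; ++e) lstep[n_d + 2 * M.N + e] = std::log(0.8);
  lstep[P - 1] = std::log(0.8);

  std::vector<int> acc_w(P_all, 0), att_w(P_all, 0);   // adaptation window
  std::vector<long> acc_s(P_all, 0), att_s(P_all, 0);  // sampling phase
  NumericMatrix draws(n_samples, P);

  RNGScope scope;
  int total = n_burnin + n_samples;
  bool has_multi = false;
  for (int s = 0; s < M.n_study; ++s)
    if (M.study_rows[s].size() > 1) has_multi = true;

  for (int iter = 0; iter < total; ++iter) {
    bool burn = iter < n_burnin;

    // --- basic contrasts d ---
    for (int j = 0; j < n_d; ++j) {
      double step = std::exp(lstep[j]);
      double cur = S.d[j];
      double prop = cur + step * R::norm_rand();
      double dlp = dnorm_log(prop, 0.0, M.effect_sd) -
                   dnorm_log(cur, 0.0, M.effect_sd);
      for (int idx : M.d_adj[j]) {
        double tau_i = S.tau[M.ep[idx]];
        double mu_cur = contrast_mean(M, S, idx);
        S.d[j] = prop;
        double mu_prop = contrast_mean(M, S, idx);
        S.d[j] = cur;
        dlp += dnorm_log(S.delta[idx], mu_prop, tau_i) -
               dnorm_log(S.delta[idx], mu_cur, tau_i);
      }
      ++att_w[j]; if (!burn) ++att_s[j];
      if (std::log(unif_rand()) < dlp) {
        S.d[j] = prop; ++acc_w[j]; if (!burn) ++acc_s[j];
      }
    }

    // --- joint translation of d_j with its study effects ---
    // shifts d_j and every adjacent delta by the same (signed) amount, so
    // the random-effects residuals are invariant and the move is governed
    // by the observation blocks and the d prior; essential when tau is
    // small and d/delta are nearly deterministically coupled
    for (int j = 0; j < n_d; ++j) {
      int p = P + j;
      double eps = std::exp(lstep[p]) * R::norm_rand();
      std::vector<int> studies_j;
      for (int idx : M.d_adj[j]) {
        int s = M.study[idx];
        bool seen = false;
        for (int t : studies_j) if (t == s) { seen = true; break; }
        if (!seen) studies_j.push_back(s);
      }
      double before = dnorm_log(S.d[j], 0.0, M.effect_sd);
      for (int s : studies_j) before += obs_block(M, S, s);
      S.d[j] += eps;
      for (size_t k = 0; k < M.d_adj[j].size(); ++k)
        S.delta[M.d_adj[j][k]] += M.d_sign[j][k] * eps;
      double after = dnorm_log(S.d[j], 0.0, M.effect_sd);
      for (int s : studies_j) after += obs_block(M, S, s);
      ++att_w[p]; if (!burn) ++att_s[p];
      if (std::log(unif_rand()) < after - before) {
        ++acc_w[p]; if (!burn) ++acc_s[p];
      } else {
        S.d[j] -= eps;
        for (size_t k = 0; k < M.d_adj[j].size(); ++k)
          S.delta[M.d_adj[j][k]] -= M.d_sign[j][k] * eps;
      }
    }

    // --- study effects delta ---
    for (int i = 0; i < M.N; ++i) {
      int p = n_d + i;
      double step = std::exp(lstep[p]);
      double cur = S.delta[i];
      double prop = cur + step * R::norm_rand();
      double tau_i = S.tau[M.ep[i]];
      double mu = contrast_mean(M, S, i);
      double before = obs_block(M, S, M.study[i]);
      S.delta[i] = prop;
      double after = obs_block(M, S, M.study[i]);
      double dlp = after - before +
                   dnorm_log(prop, mu, tau_i) - dnorm_log(cur, mu, tau_i);
      ++att_w[p]; if (!burn) ++att_s[p];
      if (std::log(unif_rand()) < dlp) { ++acc_w[p]; if (!burn) ++acc_s[p]; }
      else S.delta[i] = cur;
    }

    // --- within-study variances s2 (log scale) ---
    for (int i = 0; i < M.N; ++i) {
      int p = n_d + M.N + i;
      double step = std::exp(lstep[p]);
      double cur = S.s2[i];
      double prop = cur * std::exp(step * R::norm_rand());
      double before = obs_block(M, S, M.study[i]) +
                      dinvgamma_log(cur, M.alpha[i], M.beta[i]) + std::log(cur);
      S.s2[i] = prop;
      double after = obs_block(M, S, M.study[i]) +
                     dinvgamma_log(prop, M.alpha[i], M.beta[i]) + std::log(prop);
      double dlp = after - before;
      ++att_w[p]; if (!burn) ++att_s[p];
      if (std::log(unif_rand()) < dlp) { ++acc_w[p]; if (!burn) ++acc_s[p]; }
      else S.s2[i] = cur;
    }

    // --- between-study SDs tau (logit of (0, tau_upper)) ---
    for (int e = 0; e < n_ep; ++e) {
      int p = n_d + 2 * M.N + e;
      double step = std::exp(lstep[p]);
      double u_cur = S.u_tau[e];
      double u_prop = u_cur + step * R::norm_rand();
      double sig_cur = sigmoid(u_cur), sig_prop = sigmoid(u_prop);
      double t_cur = M.tau_upper * sig_cur;
      double t_prop = M.tau_upper * sig_prop;
      double dlp = std::log(sig_prop) + std::log1p(-sig_prop) -
                   std::log(sig_cur) - std::log1p(-sig_cur);
      for (int idx : M.ep_rows[e]) {
        double mu = contrast_mean(M, S, idx);
        dlp += dnorm_log(S.delta[idx], mu, t_prop) -
               dnorm_log(S.delta[idx], mu, t_cur);
      }
      ++att_w[p]; if (!burn) ++att_s[p];
      if (std::log(unif_rand()) < dlp) {
        S.u_tau[e] = u_prop; S.tau[e] = t_prop;
        ++acc_w[p]; if (!burn) ++acc_s[p];
      }
    }

    // --- within-study correlation rho (logit of (rho_lo, rho_hi)) ---
    {
      int p = P - 1;
      double step = std::exp(lstep[p]);
      double u_cur = S.u_rho;
      double u_prop = u_cur + step * R::norm_rand();
      double sig_cur = sigmoid(u_cur), sig_prop = sigmoid(u_prop);
      double r_cur = M.rho_lo + (M.rho_hi - M.rho_lo) * sig_cur;
      double r_prop = M.rho_lo + (M.rho_hi - M.rho_lo) * sig_prop;
      double dlp = std::log(sig_prop) + std::log1p(-sig_prop) -
                   std::log(sig_cur) - std::log1p(-sig_cur);
      if (has_multi) {
        double before = 0.0, after = 0.0;
        for (int s = 0; s < M.n_study; ++s) {
          if (M.study_rows[s].size() < 2) continue;
          before += obs_block(M, S, s);
        }
        S.rho = r_prop;
        for (int s = 0; s < M.n_study; ++s) {
          if (M.study_rows[s].size() < 2) continue;
          after += obs_block(M, S, s);
        }
        S.rho = r_cur;
        dlp += after - before;
      }
      ++att_w[p]; if (!burn) ++att_s[p];
      if (std::log(unif_rand()) < dlp) {
        S.u_rho = u_prop; S.rho = r_prop;
        ++acc_w[p]; if (!burn) ++acc_s[p];
      }
    }

    // --- burn-in step-size adaptation ---
    if (burn && (iter + 1) % adapt_interval == 0) {
      for (int p = 0; p < P_all; ++p) {
        if (att_w[p] > 0) {
          double rate = (double)acc_w[p] / att_w[p];
          lstep[p] += rate - target_accept;
          if (lstep[p] < -12.0) lstep[p] = -12.0;
          if (lstep[p] > 4.0) lstep[p] = 4.0;
        }
        acc_w[p] = 0; att_w[p] = 0;
      }
    }

    // --- store ---
    if (!burn) {
      int r = iter - n_burnin;
      int c = 0;
      for (int j = 0; j < n_d; ++j) draws(r, c++) = S.d[j];
      for (int i = 0; i < M.N; ++i) draws(r, c++) = S.delta[i];
      for (int i = 0; i < M.N; ++i) draws(r, c++) = S.s2[i];
      for (int e = 0; e < n_ep; ++e) draws(r, c++) = S.tau[e];
      draws(r, c++) = S.rho;
    }
  }

  NumericVector acc_rate(P_all);
  for (int p = 0; p < P_all; ++p)
    acc_rate[p] = att_s[p] > 0 ? (double)acc_s[p] / att_s[p] : NA_REAL;
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate);
}
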