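// Compiled Metropolis-within-Gibbs cores for the open-population
// capture-recapture models (non-spatial CR / CR_dedge and spatial SCR).
//
// Latent structure shared by both chains:
//  * per-individual yearly state in {A = not yet entered, L = alive,
//    D = dead}; sampled jointly per individual by forward filtering /
//    backward sampling, which enforces the no-re-entry (availability) rule;
//  * survival phi_t and entry gamma_t have Uniform(0,1) priors and
//    conjugate Beta full conditionals given the states;
//  * detection parameters are updated by random-walk Metropolis on their
//    prior support, with step sizes adapted only during burn-in.
//
// All randomness comes from R's RNG (RNGScope), so chains are reproducible
// via set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log(1 - p) with a series fast path for the tiny p that dominate the
// all-zero SCR cells (absolute error < 1e-16 for p < 1e-5)
static inline double log1m(double p) {
  return (p < 1e-5) ? -p * (1.0 + 0.5 * p) : std::log1p(-p);
}

// ---- step-size adaptation (Robbins-Monro flavoured, frozen after burn-in)
struct Adapt {
  double step;
  int acc = 0, tries = 0;
  explicit Adapt(double s = 0.1) : step(s) {}
  void tally(bool accepted) { tries++; if (accepted) acc++; }
  void maybe_adapt(bool in_burnin) {
    if (!in_burnin || tries < 50) return;
    double rate = (double)acc / tries;
    step *= std::exp(rate > 0.40 ? 0.15 : -0.15);
    acc = 0; tries = 0;
  }
  double rate_total = 0; int n_total = 0;      // post-burn-in bookkeeping
  void tally_final(bool accepted) { rate_total += accepted; n_total++; }
  double final_rate() const { return n_total ? rate_total / n_total : NA_REAL; }
};

// ---- FFBS for one individual ------------------------------------------------
// states: 0 = A (available, not entered), 1 = L (alive), 2 = D (dead)
// ll1[t]: log-lik of the year-t detection history given alive
// det[t]: 1 if the individual was detected in year t (forces state L)
// phi[T-1], gam[T]; out[t] receives the sampled state path.
static void ffbs_one(int T, const double* ll1, const int* det,
                     const double* phi, const double* gam, int* out,
                     std::vector<double>& fwd /* 3*T scratch */) {
  for (int t = 0; t < T; ++t) {
    double eA, eL, eD;
    if (det[t]) { eA = 0.0; eL = 1.0; eD = 0.0; }   // shift cancels
    else {
      double shift = ll1[t] > 0 ? ll1[t] : 0.0;
      eA = std::exp(-shift); eD = eA; eL = std::exp(ll1[t] - shift);
    }
    double a, l, d;
    if (t == 0) {
      a = (1.0 - gam[0]) * eA; l = gam[0] * eL; d = 0.0;
    } else {
      double pa = fwd[3 * (t - 1)], pl = fwd[3 * (t - 1) + 1],
             pd = fwd[3 * (t - 1) + 2];
      a = pa * (1.0 - gam[t]) * eA;
      l = (pa * gam[t] + pl * phi[t - 1]) * eL;
      d = (pl * (1.0 - phi[t - 1]) + pd) * eD;
    }
    double s = a + l + d;
    if (s <= 0) { a = 1.0; l = 0.0; d = 0.0; s = 1.0; }  // unreachable guard
    fwd[3 * t] = a / s; fwd[3 * t + 1] = l / s; fwd[3 * t + 2] = d / s;
  }
  // backward sample
  double u = R::runif(0, 1);
  double pa = fwd[3 * (T - 1)], pl = fwd[3 * (T - 1) + 1];
  out[T - 1] = (u < pa) ? 0 : (u < pa + pl ? 1 : 2);
  for (int t = T - 2; t >= 0; --t) {
    double wa = 0, wl = 0, wd = 0;
    double fa = fwd[3 * t], fl = fwd[3 * t + 1], fd = fwd[3 * t + 2];
    switch (out[t + 1]) {
      case 0: wa = fa * (1.0 - gam[t + 1]); break;
      case 1: wa = fa * gam[t + 1]; wl = fl * phi[t]; break;
      case 2: wl = fl * (1.0 - phi[t]); wd = fd; break;
    }
    double s = wa + wl + wd;
    if (s <= 0) { out[t] = out[t + 1] == 2 ? 1 : 0; continue; }
    double v = R::runif(0, 1) * s;
    out[t] = (v < wa) ? 0 : (v < wa + wl ? 1 : 2);
  }
}

// conjugate phi/gamma updates + derived counts from the state matrix
static void update_phi_gamma(int n, int T, const std::vector<int>& state,
                             std::vector<double>& phi, std::vector<double>& gam,
                             std::vector<int>& Nt, std::vector<int>& Bt) {
  for (int t = 0; t < T; ++t) { Nt[t] = 0; Bt[t] = 0; }
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      if (state[i * T + t] == 1) Nt[t]++;
  Bt[0] = Nt[0];
  gam[0] = R::rbeta(1.0 + Nt[0], 1.0 + (n - Nt[0]));
  for (int t = 1; t < T; ++t) {
    int surv = 0, died = 0, entered = 0, avail = 0;
    for (int i = 0; i < n; ++i) {
      int prev = state[i * T + t - 1], cur = state[i * T + t];
      if (prev == 1) { if (cur == 1) surv++; else died++; }
      else if (prev == 0) { avail++; if (cur == 1) entered++; }
    }
    Bt[t] = entered;
    phi[t - 1] = R::rbeta(1.0 + surv, 1.0 + died);
    gam[t] = R::rbeta(1.0 + entered, 1.0 + (avail - entered));
  }
}

static void init_states(int n, int T, const IntegerMatrix& det_yr,
                        std::vector<int>& state) {
  for (int i = 0; i < n; ++i) {
    int first = -1, last = -1;
    for (int t = 0; t < T; ++t)
      if (det_yr(i, t)) { if (first < 0) first = t; last = t; }
    for (int t = 0; t < T; ++t) {
      if (first < 0) state[i * T + t] = 0;                 // augmented: A
      else if (t < first) state[i * T + t] = 0;
      else if (t <= last) state[i * T + t] = 1;
      else state[i * T + t] = 2;
    }
  }
}

// =============================================================================
// Non-spatial chain (CR / CR_dedge)
//
// Detection cells are pre-aggregated into "groups": a group is a set of
// (occasion, trap type) cells within one year sharing the same baseline
// beta index and the same effort exponent, for one sex stratum. ll1(i, t)
// then only needs per-group detection counts.
// =============================================================================

struct CrGroups {
  IntegerVector t, s, b, ncells;
  NumericVector e;
  IntegerMatrix cnt;   // n x NG detection counts (rows past n_obs are zero)
  int NG;
};

// log-lik of individual i's year-t history given alive, for sex stratum s
static double cr_ll1(const CrGroups& G, int i, int t, int s,
                     const std::vector<double>& g0, // invlogit(beta), len nb
                     double bd, double dedge_i, bool use_dedge,
                     const std::vector<double>& beta) {
  double ll = 0.0;
  for (int g = 0; g < G.NG; ++g) {
    if (G.t[g] != t || G.s[g] != s) continue;
    double p;
    if (use_dedge) p = invlogit(beta[G.b[g]] + bd * dedge_i);
    else p = g0[G.b[g]];
    double e = G.e[g];
    double peff = (std::fabs(e - 1.0) < 1e-12) ? p : 1.0 - std::pow(1.0 - p, e);
    peff = std::min(std::max(peff, 1e-12), 1.0 - 1e-12);
    int y1 = G.cnt(i, g), y0 = G.ncells[g] - y1;
    ll += y1 * std::log(peff) + y0 * std::log1p(-peff);
  }
  return ll;
}

// gamma log-density kernels for the DEDGE model
static double dgamma_log(double x, double shape, double rate) {
  if (x <= 0) return R_NegInf;
  return (shape - 1.0) * std::log(x) - rate * x +
         shape * std::log(rate) - R::lgammafn(shape);
}
static double dedge_prior_loglik(const std::vector<double>& dedge,
                                 const std::vector<bool>& observed,
                                 double shape, double rate, double dmax,
                                 int n) {
  double lp = 0.0;
  double ltrunc = R::pgamma(dmax, shape, 1.0 / rate, 1, 1);
  for (int i = 0; i < n; ++i) {
    lp += dgamma_log(dedge[i], shape, rate);
    if (!observed[i]) lp -= ltrunc;     // truncated prior for imputed values
  }
  return lp;
}

// [[Rcpp::export(name = ".cr_chain_cpp")]]
List cr_chain_cpp(List data, List cfg) {
  RNGScope scope;
  if (as<int>(data["T"]) > 8) stop("at most 8 years supported");
  const int n = as<int>(data["n"]);
  const int T = as<int>(data["T"]);
  IntegerMatrix det_yr = data["det_yr"];
  CrGroups G;
  G.t = data["grp_t"]; G.s = data["grp_s"]; G.b = data["grp_b"];
  G.ncells = data["grp_ncells"]; G.e = data["grp_e"];
  G.cnt = as<IntegerMatrix>(data["grp_cnt"]);
  G.NG = G.t.size();
  const int nb = as<int>(data["nb"]);
  const int S = as<int>(data["S"]);
  IntegerVector sexg0 = data["sex_group"];     // 0-based; -1 = latent
  const bool use_dedge = as<bool>(cfg["use_dedge"]);
  NumericVector dedge_obs = data["dedge"];     // NA for latent
  const double dmax = as<double>(cfg["dedge_max"]);
  const int niter = as<int>(cfg["n_iter"]);
  const int nburn = as<int>(cfg["n_burnin"]);
  const int ft_thin = as<int>(cfg["ft_thin"]);
  const int z_thin = cfg.containsElementNamed("z_thin") ? as<int>(cfg["z_thin"]) : 0;
  const double beta_lim = 10.0, sr_lim = 30.0;

  // --- state
  std::vector<double> beta(nb);
  for (int b = 0; b < nb; ++b) beta[b] = R::runif(-3.0, -0.5);
  double bd = 0.0, shape = R::runif(1.0, 4.0), rate = R::runif(0.3, 1.0);
  double pmale = 0.5;
  std::vector<double> dedge(n, 0.0);
  std::vector<bool> dobs(n, false);
  std::vector<int> sexg(n, 0);
  std::vector<bool> sex_latent(n, false);
  int n_latent_sex = 0;
  for (int i = 0; i < n; ++i) {
    if (sexg0[i] >= 0) sexg[i] = sexg0[i];
    else { sex_latent[i] = true; n_latent_sex++; sexg[i] = R::unif_rand() < 0.5; }
    if (use_dedge) {
      if (R_finite(dedge_obs[i])) { dedge[i] = dedge_obs[i]; dobs[i] = true; }
      else dedge[i] = R::runif(0.1 * dmax, 0.6 * dmax);
    }
  }
  std::vector<double> phi(std::max(T - 1, 1), 0.5), gam(T, 0.3);
  std::vector<int> state(n * T), Nt(T), Bt(T);
  std::vector<int> detv(n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) detv[i * T + t] = det_yr(i, t);
  init_states(n, T, det_yr, state);
  std::vector<double> g0(nb);
  std::vector<double> ll1(n * T), fwd(3 * T);
  std::vector<double> ll1_scr(n * T);

  Adapt a_beta(0.15), a_bd(0.05), a_shape(0.25), a_rate(0.12), a_dedge(2.0),
        a_rot(0.05);

  const int nkeep = niter - nburn;
  const int npar = nb + 4 + (T - 1) + T + T + T + 2; // beta,bd,shape,rate,pmale,
                                                     // phi,gam,N,B,Tobs,Trep
  NumericMatrix draws(nkeep, npar);
  int nzrec = (z_thin > 0) ? (nkeep + z_thin - 1) / z_thin : 0;
  IntegerMatrix z_draws(nzrec > 0 ? nzrec : 1, nzrec > 0 ? n * T : 1);
  int zrow = 0;

  auto refresh_g0 = [&]() { for (int b = 0; b < nb; ++b) g0[b] = invlogit(beta[b]); };
  auto ll1_all = [&](std::vector<double>& out) {
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < T; ++t)
        out[i * T + t] = cr_ll1(G, i, t, sexg[i], g0, bd, dedge[i],
                                use_dedge, beta);
  };
  auto total_alive_ll = [&](const std::vector<double>& l) {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < T; ++t)
        if (state[i * T + t] == 1) s += l[i * T + t];
    return s;
  };

  refresh_g0();
  ll1_all(ll1);

  for (int iter = 0; iter < niter; ++iter) {
    const bool burn = iter < nburn;

    // ---- beta (one RW-MH update per baseline)
    for (int b = 0; b < nb; ++b) {
      double prop = beta[b] + R::norm_rand() * a_beta.step;
      bool ok = std::fabs(prop) <= beta_lim;
      bool acc = false;
      if (ok) {
        double old_b = beta[b];
        beta[b] = prop; refresh_g0();
        ll1_all(ll1_scr);
        double dll = total_alive_ll(ll1_scr) - total_alive_ll(ll1);
        if (std::log(R::unif_rand()) < dll) { acc = true; std::swap(ll1, ll1_scr); }
        else { beta[b] = old_b; refresh_g0(); }
      }
      a_beta.tally(acc); if (!burn) a_beta.tally_final(acc);
    }
    a_beta.maybe_adapt(burn);

    if (use_dedge) {
      // ---- slope on distance-to-edge
      {
        double prop = bd + R::norm_rand() * a_bd.step;
        bool acc = false;
        if (std::fabs(prop) <= beta_lim) {
          double old = bd; bd = prop;
          ll1_all(ll1_scr);
          double dll = total_alive_ll(ll1_scr) - total_alive_ll(ll1);
          if (std::log(R::unif_rand()) < dll) { acc = true; std::swap(ll1, ll1_scr); }
          else bd = old;
        }
        a_bd.tally(acc); if (!burn) a_bd.tally_final(acc);
        a_bd.maybe_adapt(burn);
      }
      // ---- joint slope/intercept rotation: the slope trades off against
      // the baselines through the mean covariate value, so shift both along
      // that ridge (dedge itself is untouched; the proposal is symmetric)
      {
        double dbar = 0.0;
        for (int i = 0; i < n; ++i) dbar += dedge[i];
        dbar /= n;
        double delta = R::norm_rand() * a_rot.step;
        double bd1 = bd + delta;
        bool ok = std::fabs(bd1) <= beta_lim;
        for (int b = 0; b < nb && ok; ++b)
          if (std::fabs(beta[b] - delta * dbar) > beta_lim) ok = false;
        bool acc = false;
        if (ok) {
          double bd0 = bd;
          std::vector<double> beta0(beta);
          bd = bd1;
          for (int b = 0; b < nb; ++b) beta[b] -= delta * dbar;
          refresh_g0();
          ll1_all(ll1_scr);
          double dll = total_alive_ll(ll1_scr) - total_alive_ll(ll1);
          if (std::log(R::unif_rand()) < dll) {
            acc = true; std::swap(ll1, ll1_scr);
          } else { bd = bd0; beta = beta0; refresh_g0(); }
        }
        a_rot.tally(acc); if (!burn) a_rot.tally_final(acc);
        a_rot.maybe_adapt(burn);
      }
      // ---- gamma hyper-parameters of the DEDGE distribution.
      // shape and rate sit on a tight ridge (the data pin the mean
      // shape/rate); mix with two multiplicative moves: scale both (mean
      // preserved) and scale the rate alone (mean move), with the
      // log-scale Hastings corrections.
      for (int which = 0; which < 2; ++which) {
        Adapt& A = which == 0 ? a_shape : a_rate;
        double f = std::exp(R::norm_rand() * A.step);
        double s1 = which == 0 ? shape * f : shape;
        double r1 = rate * f;
        bool acc = false;
        if (s1 > 0 && s1 <= sr_lim && r1 > 0 && r1 <= sr_lim) {
          double lp0 = dedge_prior_loglik(dedge, dobs, shape, rate, dmax, n);
          double lp1 = dedge_prior_loglik(dedge, dobs, s1, r1, dmax, n);
          double hastings = (which == 0 ? 2.0 : 1.0) * std::log(f);
          if (std::log(R::unif_rand()) < lp1 - lp0 + hastings) {
            acc = true; shape = s1; rate = r1;
          }
        }
        A.tally(acc); if (!burn) A.tally_final(acc);
        A.maybe_adapt(burn);
      }
      // ---- imputed DEDGE for augmented individuals (latent, RW-MH)
      double ltrunc = R::pgamma(dmax, shape, 1.0 / rate, 1, 1); (void)ltrunc;
      for (int i = 0; i < n; ++i) {
        if (dobs[i]) continue;
        double prop = dedge[i] + R::norm_rand() * a_dedge.step;
        bool acc = false;
        if (prop >= 0 && prop <= dmax) {
          double dpr = dgamma_log(prop, shape, rate) -
                       dgamma_log(dedge[i], shape, rate);
          double dll = 0.0;
          double lnew[8]; // T <= 8 supported
          for (int t = 0; t < T; ++t) {
            lnew[t] = cr_ll1(G, i, t, sexg[i], g0, bd, prop, use_dedge, beta);
            if (state[i * T + t] == 1) dll += lnew[t] - ll1[i * T + t];
          }
          if (std::log(R::unif_rand()) < dpr + dll) {
            acc = true; dedge[i] = prop;
            for (int t = 0; t < T; ++t) ll1[i * T + t] = lnew[t];
          }
        }
        a_dedge.tally(acc); if (!burn) a_dedge.tally_final(acc);
      }
      a_dedge.maybe_adapt(burn);
    }

    // ---- latent sex (Gibbs over the two strata) and p_male
    if (S > 1 && n_latent_sex > 0) {
      for (int i = 0; i < n; ++i) {
        if (!sex_latent[i]) continue;
        double llF = 0.0, llM = 0.0, lF[8], lM[8];
        for (int t = 0; t < T; ++t) {
          lF[t] = cr_ll1(G, i, t, 0, g0, bd, dedge[i], use_dedge, beta);
          lM[t] = cr_ll1(G, i, t, 1, g0, bd, dedge[i], use_dedge, beta);
          if (state[i * T + t] == 1) { llF += lF[t]; llM += lM[t]; }
        }
        double mx = std::max(llF, llM);
        double wM = pmale * std::exp(llM - mx);
        double wF = (1.0 - pmale) * std::exp(llF - mx);
        int newsex = (R::unif_rand() * (wF + wM) < wM) ? 1 : 0;
        sexg[i] = newsex;
        const double* l = newsex ? lM : lF;
        for (int t = 0; t < T; ++t) ll1[i * T + t] = l[t];
      }
    }
    if (S > 1) {
      int males = 0;
      for (int i = 0; i < n; ++i) males += sexg[i];
      pmale = R::rbeta(1.0 + males, 1.0 + (n - males));
    }

    // ---- latent alive states, then survival/entry rates
    for (int i = 0; i < n; ++i)
      ffbs_one(T, &ll1[i * T], &detv[i * T], phi.data(), gam.data(),
               &state[i * T], fwd);
    update_phi_gamma(n, T, state, phi, gam, Nt, Bt);

    // ---- record
    if (iter >= nburn) {
      int r = iter - nburn, c = 0;
      for (int b = 0; b < nb; ++b) draws(r, c++) = beta[b];
      draws(r, c++) = bd; draws(r, c++) = shape; draws(r, c++) = rate;
      draws(r, c++) = pmale;
      for (int t = 0; t < T - 1; ++t) draws(r, c++) = phi[t];
      for (int t = 0; t < T; ++t) draws(r, c++) = gam[t];
      for (int t = 0; t < T; ++t) draws(r, c++) = Nt[t];
      for (int t = 0; t < T; ++t) draws(r, c++) = Bt[t];
      // Freeman-Tukey discrepancy on a thinned schedule
      double tobs = NA_REAL, trep = NA_REAL;
      if (ft_thin > 0 && (r % ft_thin) == 0) {
        tobs = 0.0; trep = 0.0;
        for (int g = 0; g < G.NG; ++g) {
          int t = G.t[g];
          for (int i = 0; i < n; ++i) {
            if (state[i * T + t] != 1 || sexg[i] != G.s[g]) continue;
            double p;
            if (use_dedge) p = invlogit(beta[G.b[g]] + bd * dedge[i]);
            else p = g0[G.b[g]];
            double e = G.e[g];
            double peff = (std::fabs(e - 1.0) < 1e-12)
                            ? p : 1.0 - std::pow(1.0 - p, e);
            int y1 = G.cnt(i, g), nc = G.ncells[g];
            double sq1 = (1.0 - std::sqrt(peff)) * (1.0 - std::sqrt(peff));
            tobs += y1 * sq1 + (nc - y1) * peff;
            int yrep = (int)R::rbinom(nc, peff);
            trep += yrep * sq1 + (nc - yrep) * peff;
          }
        }
      }
      draws(r, c++) = tobs; draws(r, c++) = trep;
      if (z_thin > 0 && (r % z_thin) == 0 && zrow < nzrec) {
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t)
            z_draws(zrow, i * T + t) = state[i * T + t] == 1 ? 1 : 0;
        zrow++;
      }
    }
  }

  List out = List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["beta"] = a_beta.final_rate(), _["beta_dedge"] = a_bd.final_rate(),
      _["shape"] = a_shape.final_rate(), _["rate"] = a_rate.final_rate(),
      _["dedge"] = a_dedge.final_rate()));
  if (z_thin > 0) out["z"] = z_draws;
  return out;
}

// =============================================================================
// Spatial chain (SCR)
//
// Half-normal detection from latent activity centres on a rectangular state
// space. Per trap j, year t and sex stratum s the active occasions are
// pre-grouped by their baseline (g0) index, so the all-zero part of the
// likelihood is a weighted sum of log(1 - g0_b * E_ij) terms with
// E_ij = exp(-d_ij^2 / (2 sigma_s^2)); observed detections add sparse
// corrections.
// =============================================================================

struct ScrPairs {
  // flattened (j, t, s) -> runs of (beta index, active-occasion count)
  std::vector<int> start, len, pb, pc;
  int J, T, S;
  inline int cell(int j, int t, int s) const { return (s * T + t) * J + j; }
};

struct ScrDets {
  // per (i, t): runs of detections (trap j, beta index b) per sex stratum
  // (beta index depends on sex, so store occasion k and map at use time)
  std::vector<int> start, len, dj, dk;
  int T;
  inline int cell(int i, int t) const { return i * T + t; }
};

// [[Rcpp::export(name = ".scr_chain_cpp")]]
List scr_chain_cpp(List data, List cfg) {
  RNGScope scope;
  const int n = as<int>(data["n"]);
  const int T = as<int>(data["T"]);
  if (T > 8) stop("at most 8 years supported");
  IntegerMatrix det_yr = data["det_yr"];
  NumericMatrix trapxy = data["trapxy"];
  const int J = trapxy.nrow();
  IntegerVector trap_type = data["trap_type"];       // 0-based
  IntegerVector act = data["act"];                   // J*K*T 0/1
  IntegerVector bidx = data["bidx"];                 // K*M*S -> 0-based
  const int K = as<int>(data["K"]);
  const int M = as<int>(data["M"]);
  const int S = as<int>(data["S"]);
  const int nb = as<int>(data["nb"]);
  IntegerVector sexg0 = data["sex_group"];           // -1 = latent
  IntegerMatrix dets = data["dets"];                 // nd x 4: i j k t, 0-based
  const bool sigma_by_sex = as<bool>(cfg["sigma_by_sex"]);
  const double xlo = as<double>(cfg["xlo"]), xhi = as<double>(cfg["xhi"]);
  const double ylo = as<double>(cfg["ylo"]), yhi = as<double>(cfg["yhi"]);
  const double sigma_max = as<double>(cfg["sigma_max"]);
  NumericMatrix centres0 = data["centres_init"];     // n x 2 (NA -> uniform)
  const int niter = as<int>(cfg["n_iter"]);
  const int nburn = as<int>(cfg["n_burnin"]);
  const int ft_thin = as<int>(cfg["ft_thin"]);
  const int centre_thin = as<int>(cfg["centre_thin"]);
  const int z_thin = cfg.containsElementNamed("z_thin") ? as<int>(cfg["z_thin"]) : 0;
  const double beta_lim = 10.0;

  // ---- precompute group structure
  ScrPairs P; P.J = J; P.T = T; P.S = S;
  P.start.assign(J * T * S, 0); P.len.assign(J * T * S, 0);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < J; ++j) {
        std::vector<int> cnt(nb, 0);
        for (int k = 0; k < K; ++k) {
          if (!act[j + J * (k + K * t)]) continue;
          int b = bidx[k + K * (trap_type[j] + M * s)];
          cnt[b]++;
        }
        P.start[P.cell(j, t, s)] = (int)P.pb.size();
        int l = 0;
        for (int b = 0; b < nb; ++b)
          if (cnt[b]) { P.pb.push_back(b); P.pc.push_back(cnt[b]); l++; }
        P.len[P.cell(j, t, s)] = l;
      }

  ScrDets D; D.T = T;
  D.start.assign(n * T, 0); D.len.assign(n * T, 0);
  {
    const int nd = dets.nrow();
    std::vector<std::vector<std::pair<int,int>>> tmp(n * T);
    for (int r = 0; r < nd; ++r)
      tmp[dets(r, 0) * T + dets(r, 3)].push_back({dets(r, 1), dets(r, 2)});
    for (int c = 0; c < n * T; ++c) {
      D.start[c] = (int)D.dj.size(); D.len[c] = (int)tmp[c].size();
      for (auto& pr : tmp[c]) { D.dj.push_back(pr.first); D.dk.push_back(pr.second); }
    }
  }

  // ---- state
  std::vector<double> beta(nb);
  for (int b = 0; b < nb; ++b) beta[b] = R::runif(-3.5, -1.0);
  const int nsig = sigma_by_sex ? S : 1;
  std::vector<double> sigma(nsig);
  for (int g = 0; g < nsig; ++g) sigma[g] = R::runif(0.25, 0.75) * sigma_max;
  double pmale = 0.5;
  std::vector<int> sexg(n, 0);
  std::vector<bool> sex_latent(n, false);
  int n_latent_sex = 0;
  for (int i = 0; i < n; ++i) {
    if (sexg0[i] >= 0) sexg[i] = sexg0[i];
    else { sex_latent[i] = true; n_latent_sex++; sexg[i] = R::unif_rand() < 0.5; }
  }
  std::vector<double> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    if (R_finite(centres0(i, 0))) {
      cx[i] = std::min(std::max(centres0(i, 0), xlo), xhi);
      cy[i] = std::min(std::max(centres0(i, 1), ylo), yhi);
    } else { cx[i] = R::runif(xlo, xhi); cy[i] = R::runif(ylo, yhi); }
  }
  std::vector<double> phi(std::max(T - 1, 1), 0.5), gam(T, 0.3);
  std::vector<int> state(n * T), Nt(T), Bt(T), detv(n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) detv[i * T + t] = det_yr(i, t);
  init_states(n, T, det_yr, state);

  std::vector<double> g0(nb);
  auto refresh_g0 = [&]() { for (int b = 0; b < nb; ++b) g0[b] = invlogit(beta[b]); };
  refresh_g0();

  std::vector<double> E(n * J), Escr(n * J), Erow(J), ll1(n * T),
      ll1_scr(n * T), fwd(3 * T);

  auto fill_E_row = [&](int i, double sg, double x, double y, double* out) {
    double inv2s2 = 1.0 / (2.0 * sg * sg);
    for (int j = 0; j < J; ++j) {
      double dx = x - trapxy(j, 0), dy = y - trapxy(j, 1);
      out[j] = std::exp(-(dx * dx + dy * dy) * inv2s2);
    }
  };
  auto sig_of = [&](int i) { return sigma[sigma_by_sex ? sexg[i] : 0]; };

  // year-t log-lik of individual i given alive, using row Ei and stratum s
  auto ll1_it = [&](int i, int t, int s, const double* Ei) {
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      int c0 = P.cell(j, t, s), st = P.start[c0], l = P.len[c0];
      for (int q = 0; q < l; ++q) {
        double p = g0[P.pb[st + q]] * Ei[j];
        ll += P.pc[st + q] * log1m(std::min(p, 1.0 - 1e-12));
      }
    }
    int c1 = D.cell(i, t), st = D.start[c1], l = D.len[c1];
    for (int q = 0; q < l; ++q) {
      int j = D.dj[st + q], k = D.dk[st + q];
      int b = bidx[k + K * (trap_type[j] + M * s)];
      double p = g0[b] * Ei[j];
      p = std::min(std::max(p, 1e-300), 1.0 - 1e-12);
      ll += std::log(p) - std::log1p(-p);
    }
    return ll;
  };
  auto ll1_all = [&](std::vector<double>& out) {
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < T; ++t)
        out[i * T + t] = ll1_it(i, t, sexg[i], &E[i * J]);
  };
  auto total_alive_ll = [&](const std::vector<double>& l) {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < T; ++t)
        if (state[i * T + t] == 1) s += l[i * T + t];
    return s;
  };

  for (int i = 0; i < n; ++i) fill_E_row(i, sig_of(i), cx[i], cy[i], &E[i * J]);
  ll1_all(ll1);

  Adapt a_beta(0.15), a_cent(1.0);
  std::vector<Adapt> a_sigma(nsig, Adapt(0.2));

  const int nkeep = niter - nburn;
  const int npar = nb + nsig + 1 + (T - 1) + T + T + T + 2;
  NumericMatrix draws(nkeep, npar);
  int ncrec = (centre_thin > 0) ? (nkeep + centre_thin - 1) / centre_thin : 0;
  NumericMatrix centre_draws(ncrec > 0 ? ncrec : 1, ncrec > 0 ? 2 * n : 1);
  int crow = 0;
  int nzrec = (z_thin > 0) ? (nkeep + z_thin - 1) / z_thin : 0;
  IntegerMatrix z_draws(nzrec > 0 ? nzrec : 1, nzrec > 0 ? n * T : 1);
  int zrow = 0;

  for (int iter = 0; iter < niter; ++iter) {
    const bool burn = iter < nburn;

    // ---- activity centres (independent MH per individual)
    for (int i = 0; i < n; ++i) {
      double px = cx[i] + R::norm_rand() * a_cent.step;
      double py = cy[i] + R::norm_rand() * a_cent.step;
      bool acc = false;
      if (px >= xlo && px <= xhi && py >= ylo && py <= yhi) {
        bool any_alive = false;
        for (int t = 0; t < T; ++t) if (state[i * T + t] == 1) any_alive = true;
        if (!any_alive) {
          acc = true; cx[i] = px; cy[i] = py;
          fill_E_row(i, sig_of(i), px, py, &E[i * J]);
          for (int t = 0; t < T; ++t) ll1[i * T + t] = ll1_it(i, t, sexg[i], &E[i * J]);
        } else {
          fill_E_row(i, sig_of(i), px, py, Erow.data());
          double lnew[8], dll = 0.0;
          for (int t = 0; t < T; ++t) {
            lnew[t] = ll1_it(i, t, sexg[i], Erow.data());
            if (state[i * T + t] == 1) dll += lnew[t] - ll1[i * T + t];
          }
          if (std::log(R::unif_rand()) < dll) {
            acc = true; cx[i] = px; cy[i] = py;
            std::copy(Erow.begin(), Erow.end(), E.begin() + i * J);
            for (int t = 0; t < T; ++t) ll1[i * T + t] = lnew[t];
          }
        }
      }
      a_cent.tally(acc); if (!burn) a_cent.tally_final(acc);
    }
    a_cent.maybe_adapt(burn);

    // ---- sigma (per stratum)
    for (int g = 0; g < nsig; ++g) {
      double prop = sigma[g] + R::norm_rand() * a_sigma[g].step;
      bool acc = false;
      if (prop > 0 && prop < sigma_max) {
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          if ((sigma_by_sex ? sexg[i] : 0) != g) continue;
          fill_E_row(i, prop, cx[i], cy[i], &Escr[i * J]);
          for (int t = 0; t < T; ++t) {
            ll1_scr[i * T + t] = ll1_it(i, t, sexg[i], &Escr[i * J]);
            if (state[i * T + t] == 1)
              dll += ll1_scr[i * T + t] - ll1[i * T + t];
          }
        }
        if (std::log(R::unif_rand()) < dll) {
          acc = true; sigma[g] = prop;
          for (int i = 0; i < n; ++i) {
            if ((sigma_by_sex ? sexg[i] : 0) != g) continue;
            std::copy(Escr.begin() + i * J, Escr.begin() + (i + 1) * J,
                      E.begin() + i * J);
            for (int t = 0; t < T; ++t) ll1[i * T + t] = ll1_scr[i * T + t];
          }
        }
      }
      a_sigma[g].tally(acc); if (!burn) a_sigma[g].tally_final(acc);
      a_sigma[g].maybe_adapt(burn);
    }

    // ---- g0 baselines
    for (int b = 0; b < nb; ++b) {
      double prop = beta[b] + R::norm_rand() * a_beta.step;
      bool acc = false;
      if (std::fabs(prop) <= beta_lim) {
        double old = beta[b]; beta[b] = prop; refresh_g0();
        double dll = 0.0;
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t) {
            ll1_scr[i * T + t] = ll1_it(i, t, sexg[i], &E[i * J]);
            if (state[i * T + t] == 1)
              dll += ll1_scr[i * T + t] - ll1[i * T + t];
          }
        if (std::log(R::unif_rand()) < dll) { acc = true; std::swap(ll1, ll1_scr); }
        else { beta[b] = old; refresh_g0(); }
      }
      a_beta.tally(acc); if (!burn) a_beta.tally_final(acc);
    }
    a_beta.maybe_adapt(burn);

    // ---- latent sex + p_male
    if (S > 1 && n_latent_sex > 0) {
      std::vector<double> Ef(J), Em(J);
      for (int i = 0; i < n; ++i) {
        if (!sex_latent[i]) continue;
        fill_E_row(i, sigma[sigma_by_sex ? 0 : 0], cx[i], cy[i], Ef.data());
        fill_E_row(i, sigma[sigma_by_sex ? std::min(1, nsig - 1) : 0],
                   cx[i], cy[i], Em.data());
        double llF = 0.0, llM = 0.0, lF[8], lM[8];
        for (int t = 0; t < T; ++t) {
          lF[t] = ll1_it(i, t, 0, Ef.data());
          lM[t] = ll1_it(i, t, std::min(1, S - 1), Em.data());
          if (state[i * T + t] == 1) { llF += lF[t]; llM += lM[t]; }
        }
        double mx = std::max(llF, llM);
        double wM = pmale * std::exp(llM - mx);
        double wF = (1.0 - pmale) * std::exp(llF - mx);
        int newsex = (R::unif_rand() * (wF + wM) < wM) ? 1 : 0;
        sexg[i] = newsex;
        const double* l = newsex ? lM : lF;
        const double* Erow2 = newsex ? Em.data() : Ef.data();
        std::copy(Erow2, Erow2 + J, E.begin() + i * J);
        for (int t = 0; t < T; ++t) ll1[i * T + t] = l[t];
      }
    }
    if (S > 1) {
      int males = 0;
      for (int i = 0; i < n; ++i) males += sexg[i];
      pmale = R::rbeta(1.0 + males, 1.0 + (n - males));
    }

    // ---- latent alive states, then survival/entry rates
    for (int i = 0; i < n; ++i)
      ffbs_one(T, &ll1[i * T], &detv[i * T], phi.data(), gam.data(),
               &state[i * T], fwd);
    update_phi_gamma(n, T, state, phi, gam, Nt, Bt);

    // ---- record
    if (iter >= nburn) {
      int r = iter - nburn, c = 0;
      for (int b = 0; b < nb; ++b) draws(r, c++) = beta[b];
      for (int g = 0; g < nsig; ++g) draws(r, c++) = sigma[g];
      draws(r, c++) = pmale;
      for (int t = 0; t < T - 1; ++t) draws(r, c++) = phi[t];
      for (int t = 0; t < T; ++t) draws(r, c++) = gam[t];
      for (int t = 0; t < T; ++t) draws(r, c++) = Nt[t];
      for (int t = 0; t < T; ++t) draws(r, c++) = Bt[t];
      double tobs = NA_REAL, trep = NA_REAL;
      if (ft_thin > 0 && (r % ft_thin) == 0) {
        tobs = 0.0; trep = 0.0;
        for (int i = 0; i < n; ++i) {
          int s = sexg[i];
          for (int t = 0; t < T; ++t) {
            if (state[i * T + t] != 1) continue;
            // all-cells baseline via group counts, then detection corrections
            for (int j = 0; j < J; ++j) {
              int c0 = P.cell(j, t, s), st = P.start[c0], l = P.len[c0];
              for (int q = 0; q < l; ++q) {
                double p = g0[P.pb[st + q]] * E[i * J + j];
                int nc = P.pc[st + q];
                double sq1 = (1.0 - std::sqrt(p)) * (1.0 - std::sqrt(p));
                tobs += nc * p;
                int yrep = (int)R::rbinom(nc, p);
                trep += yrep * sq1 + (nc - yrep) * p;
              }
            }
            int c1 = D.cell(i, t), st = D.start[c1], l = D.len[c1];
            for (int q = 0; q < l; ++q) {
              int j = D.dj[st + q], k = D.dk[st + q];
              int b = bidx[k + K * (trap_type[j] + M * s)];
              double p = g0[b] * E[i * J + j];
              double sq1 = (1.0 - std::sqrt(p)) * (1.0 - std::sqrt(p));
              tobs += sq1 - p;   // replace a zero-cell term by a one-cell term
            }
          }
        }
      }
      draws(r, c++) = tobs; draws(r, c++) = trep;
      if (centre_thin > 0 && (r % centre_thin) == 0 && crow < ncrec) {
        for (int i = 0; i < n; ++i) {
          centre_draws(crow, i) = cx[i];
          centre_draws(crow, n + i) = cy[i];
        }
        crow++;
      }
      if (z_thin > 0 && (r % z_thin) == 0 && zrow < nzrec) {
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t)
            z_draws(zrow, i * T + t) = state[i * T + t] == 1 ? 1 : 0;
        zrow++;
      }
    }
  }

  List out = List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["beta"] = a_beta.final_rate(), _["centre"] = a_cent.final_rate(),
      _["sigma"] = a_sigma[0].final_rate()));
  if (centre_thin > 0) out["centres"] = centre_draws;
  if (z_thin > 0) out["z"] = z_draws;
  return out;
}
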