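#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transition intensities are Gompertz-type log-linear in age:
//
//     q_k(t) = exp(eta_k + ba_k * (t - origin))
//
// where eta_k collects the baseline log-intensity at the age origin plus any
// covariate effects for allowed transition k, and ba_k is the per-year
// log-hazard slope.  States are 0-based; the single absorbing death state is
// never represented explicitly: only the (n_alive x n_alive) block of the
// transition probability matrix is propagated, and the probability of having
// died is recovered as the row deficit 1 - rowsum.  This is exact because
// death is absorbing.

static inline void expm_2x2(double a11, double a12, double a21, double a22,
                            double out[4]) {
  // closed-form exponential of a 2x2 sub-generator block: a12 * a21 >= 0 so
  // the eigenvalues s +/- d are real, and both are <= 0, so exp(s +/- d)
  // never overflows even for extreme intensities (e.g. wild parameter draws)
  const double s  = 0.5 * (a11 + a22);
  const double d2 = 0.25 * (a11 - a22) * (a11 - a22) + a12 * a21;
  const double d  = d2 > 0.0 ? std::sqrt(d2) : 0.0;
  const double e1 = std::exp(s + d);   // exp(lambda_max), in (0, 1]
  const double e2 = std::exp(s - d);   // exp(lambda_min)
  const double es_ch = 0.5 * (e1 + e2);            // exp(s) * cosh(d)
  double es_shd;                                   // exp(s) * sinh(d) / d
  if (d > 1e-8) es_shd = 0.5 * (e1 - e2) / d;
  else          es_shd = std::exp(s) * (1.0 + d2 / 6.0);
  out[0] = es_ch + es_shd * (a11 - s);
  out[1] = es_shd * a12;
  out[2] = es_shd * a21;
  out[3] = es_ch + es_shd * (a22 - s);
}

// intensity with an overflow cap: 1e8/year already absorbs any sub-interval.
// The same capped form MUST be used both inside the generator and as the
// exact-death density factor, otherwise extreme trial parameters could make
// the density factor outrun the matching survival penalty.
static inline double intensity(double eta, double ba, double t_rel) {
  return std::min(std::exp(eta + ba * t_rel), 1e8);
}

static void fill_generator(arma::mat &A, const double *eta, const double *ba,
                           const int *tfrom, const int *tto, int K,
                           int n_alive, double t_rel) {
  A.zeros();
  for (int k = 0; k < K; ++k) {
    const double q = intensity(eta[k], ba[k], t_rel);
    const int r = tfrom[k];
    if (tto[k] < n_alive) A(r, tto[k]) += q;
    A(r, r) -= q;
  }
}

// Alive-block transition probability matrix over [a0, a1]: the interval is
// split into sub-intervals of length <= step, the generator is evaluated at
// each sub-interval midpoint age (second-order accurate for the
// age-inhomogeneous problem), exponentiated, and the pieces composed in
// age order.
static arma::mat pmat_alive(const double *eta, const double *ba,
                            const int *tfrom, const int *tto, int K,
                            int n_alive, double a0, double a1,
                            double origin, double step) {
  arma::mat P(n_alive, n_alive, arma::fill::eye);
  const double len = a1 - a0;
  if (len <= 0.0) return P;
  int m = (int)std::ceil(len / step - 1e-9);
  if (m < 1) m = 1;
  const double dt = len / m;
  arma::mat A(n_alive, n_alive);
  for (int i = 0; i < m; ++i) {
    const double tm = a0 + (i + 0.5) * dt - origin;
    if (n_alive == 1) {
      double qtot = 0.0;
      for (int k = 0; k < K; ++k)
        if (tfrom[k] == 0) qtot += std::exp(eta[k] + ba[k] * tm);
      P(0, 0) *= std::exp(-qtot * dt);
    } else if (n_alive == 2) {
      fill_generator(A, eta, ba, tfrom, tto, K, n_alive, tm);
      double E[4];
      expm_2x2(A(0, 0) * dt, A(0, 1) * dt, A(1, 0) * dt, A(1, 1) * dt, E);
      const double p00 = P(0, 0), p01 = P(0, 1);
      const double p10 = P(1, 0), p11 = P(1, 1);
      P(0, 0) = p00 * E[0] + p01 * E[2];
      P(0, 1) = p00 * E[1] + p01 * E[3];
      P(1, 0) = p10 * E[0] + p11 * E[2];
      P(1, 1) = p10 * E[1] + p11 * E[3];
    } else {
      fill_generator(A, eta, ba, tfrom, tto, K, n_alive, tm);
      P = P * arma::expmat(A * dt);
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmat_alive(const NumericVector &eta, const NumericVector &ba,
                         const IntegerVector &tfrom, const IntegerVector &tto,
                         int n_alive, double a0, double a1, double origin,
                         double step) {
  return pmat_alive(&eta[0], &ba[0], &tfrom[0], &tto[0], eta.size(), n_alive,
                    a0, a1, origin, step);
}

// Log-likelihood contributions of observation intervals.  Row i of ETA holds
// the covariate-adjusted log baseline intensities for interval i (covariates
// fixed at their value at the interval start).  Contributions:
//   alive r -> alive s observed at (a0, a1):      log P_rs(a0, a1)
//   exact death at a1 from r at a0 (last alive
//   state unknown):      log sum_s P_rs(a0, a1) * q_{s,death}(a1)
//   death observed at a1 without exact time:      log (1 - sum_s P_rs)
// An impossible path yields -Inf, not an error.
// [[Rcpp::export]]
NumericVector cpp_interval_loglik(const arma::mat &ETA,
                                  const NumericVector &ba,
                                  const IntegerVector &tfrom,
                                  const IntegerVector &tto, int n_alive,
                                  const IntegerVector &from,
                                  const IntegerVector &to,
                                  const LogicalVector &exact_death,
                                  const NumericVector &a0,
                                  const NumericVector &a1, double origin,
                                  double step) {
  const int n = ETA.n_rows, K = ETA.n_cols;
  NumericVector out(n);
  std::vector<double> eta(K);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) eta[k] = ETA(i, k);
    arma::mat P = pmat_alive(eta.data(), &ba[0], &tfrom[0], &tto[0], K,
                             n_alive, a0[i], a1[i], origin, step);
    const int r = from[i];
    double val;
    if (exact_death[i]) {
      val = 0.0;
      const double trel = a1[i] - origin;
      for (int k = 0; k < K; ++k)
        if (tto[k] == n_alive)
          val += P(r, tfrom[k]) * intensity(eta[k], ba[k], trel);
    } else if (to[i] == n_alive) {
      val = 1.0 - arma::accu(P.row(r));
    } else {
      val = P(r, to[i]);
    }
    out[i] = (val > 0.0) ? std::log(val) : R_NegInf;
  }
  return out;
}

// State-occupancy probabilities over an age grid for each alive starting
// state, by chaining the alive-block transition matrices cell by cell.
// Returns a cube: (grid age, occupied alive state, starting alive state).
// [[Rcpp::export]]
arma::cube cpp_occupancy(const NumericVector &eta, const NumericVector &ba,
                         const IntegerVector &tfrom, const IntegerVector &tto,
                         int n_alive, const NumericVector &ages, double origin,
                         double step) {
  const int n = ages.size(), K = eta.size();
  arma::cube occ(n, n_alive, n_alive, arma::fill::zeros);
  arma::mat M(n_alive, n_alive, arma::fill::eye);  // row = start state
  for (int s = 0; s < n_alive; ++s) occ(0, s, s) = 1.0;
  for (int i = 1; i < n; ++i) {
    arma::mat P = pmat_alive(&eta[0], &ba[0], &tfrom[0], &tto[0], K, n_alive,
                             ages[i - 1], ages[i], origin, step);
    M = M * P;
    for (int s = 0; s < n_alive; ++s)
      for (int j = 0; j < n_alive; ++j) occ(i, j, s) = M(s, j);
  }
  return occ;
}

// Simulate one continuous-time path segment by competing-risks sampling on a
// piecewise-constant rate grid (rates refreshed every dt years, and after
// each jump).  Returns a matrix of jumps (age, new 0-based state), where the
// death state is coded n_alive.  Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_sim_segment(int state0, double age0, double age_end,
                              const NumericVector &eta,
                              const NumericVector &ba,
                              const IntegerVector &tfrom,
                              const IntegerVector &tto, int n_alive,
                              double origin, double dt) {
  const int K = eta.size();
  std::vector<double> jump_age, jump_state;
  int s = state0;
  double t = age0;
  std::vector<double> q(K);
  while (t < age_end - 1e-12 && s < n_alive) {
    const double win = std::min(dt, age_end - t);
    double lam = 0.0;
    for (int k = 0; k < K; ++k) {
      if (tfrom[k] == s) {
        q[k] = std::exp(eta[k] + ba[k] * (t - origin));
        lam += q[k];
      } else {
        q[k] = 0.0;
      }
    }
    if (lam <= 0.0) {
      t += win;
      continue;
    }
    const double e = R::rexp(1.0) / lam;
    if (e >= win) {
      t += win;
      continue;
    }
    t += e;
    const double u = R::runif(0.0, lam);
    double cum = 0.0;
    int dest = -1;
    for (int k = 0; k < K; ++k) {
      if (q[k] > 0.0) {
        cum += q[k];
        if (u <= cum) {
          dest = tto[k];
          break;
        }
      }
    }
    if (dest < 0) dest = n_alive;  // numerical guard: treat as last exit
    jump_age.push_back(t);
    jump_state.push_back((double)dest);
    s = dest;
  }
  NumericMatrix out(jump_age.size(), 2);
  for (int i = 0; i < (int)jump_age.size(); ++i) {
    out(i, 0) = jump_age[i];
    out(i, 1) = jump_state[i];
  }
  colnames(out) = CharacterVector::create("age", "state");
  return out;
}
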