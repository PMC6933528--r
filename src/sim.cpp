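#include <Rcpp.h>
using namespace Rcpp;

// Index map for the packed parameter vector handed over from R
// (see .pack_params() in R/simulate.R; order is part of the internal ABI).
enum Par {
  P_WMAX, P_NMAX, P_RMAX,
  P_ALPHA_W, P_ALPHA_N, P_ALPHA_R,
  P_BETA_W, P_BETA_R, P_KN,
  P_TAU_W, P_TAU_N, P_TAU_R,
  P_HMAX, P_THETA_W, P_TAU_HW, P_TAU_HS,
  P_TAU_CW, P_TAU_CN, P_TAU_CR,
  P_GAM_CW, P_GAM_CN, P_GAM_CR,
  P_G_RRE, P_G_RWE, P_G_WNI, P_G_WRI, P_G_NRI, P_G_NWI,
  P_NPAR
};

// State layout: F_W F_N F_R C_W C_N C_R H
enum St { S_FW, S_FN, S_FR, S_CW, S_CN, S_CR, S_H, NSTATE };

static inline double fss(double I, double beta, double alpha, double fmax) {
  return fmax * 0.5 * (1.0 + std::tanh((I - beta) / alpha));
}

static inline double heav(double z) { return z >= 0.0 ? 1.0 : 0.0; }

// Right-hand side of the 7-dimensional system; xi are the per-population
// noise draws (Hz), frozen across the four RK4 stages of a step.
static void rhs(const double *y, const double *p, const double *xi, double *dy) {
  const double IW = p[P_G_NWI] * y[S_CN] + p[P_G_RWE] * y[S_CR] + xi[0];
  const double IN = p[P_G_WNI] * y[S_CW] + xi[1];
  const double IR = p[P_G_WRI] * y[S_CW] + p[P_G_NRI] * y[S_CN] +
                    p[P_G_RRE] * y[S_CR] + xi[2];

  dy[S_FW] = (fss(IW, p[P_BETA_W], p[P_ALPHA_W], p[P_WMAX]) - y[S_FW]) / p[P_TAU_W];
  dy[S_FN] = (fss(IN, p[P_KN] * y[S_H], p[P_ALPHA_N], p[P_NMAX]) - y[S_FN]) / p[P_TAU_N];
  dy[S_FR] = (fss(IR, p[P_BETA_R], p[P_ALPHA_R], p[P_RMAX]) - y[S_FR]) / p[P_TAU_R];

  dy[S_CW] = (std::tanh(y[S_FW] / p[P_GAM_CW]) - y[S_CW]) / p[P_TAU_CW];
  dy[S_CN] = (std::tanh(y[S_FN] / p[P_GAM_CN]) - y[S_CN]) / p[P_TAU_CN];
  dy[S_CR] = (std::tanh(y[S_FR] / p[P_GAM_CR]) - y[S_CR]) / p[P_TAU_CR];

  dy[S_H] = (p[P_HMAX] - y[S_H]) / p[P_TAU_HW] * heav(y[S_FW] - p[P_THETA_W]) -
            y[S_H] / p[P_TAU_HS] * heav(p[P_THETA_W] - y[S_FW]);
}

static void rk4(const double *y, const double *p, const double *xi,
                double dt, double *out) {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  rhs(y, p, xi, k1);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  rhs(tmp, p, xi, k2);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  rhs(tmp, p, xi, k3);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + dt * k3[i];
  rhs(tmp, p, xi, k4);
  for (int i = 0; i < NSTATE; ++i)
    out[i] = y[i] + dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Clip a state component back into [lo, hi] if the excursion is below tol;
// larger excursions are integration failures.
static void clip_box(double *y, const double *p, double tol, R_xlen_t step) {
  const double hi[NSTATE] = {p[P_WMAX], p[P_NMAX], p[P_RMAX], 1.0, 1.0, 1.0, p[P_HMAX]};
  static const char *nm[NSTATE] = {"F_W", "F_N", "F_R", "C_W", "C_N", "C_R", "H"};
  for (int i = 0; i < NSTATE; ++i) {
    if (!R_finite(y[i]))
      stop("integration failure: non-finite %s at step %.0f", nm[i], (double)step);
    if (y[i] < 0.0) {
      if (y[i] < -tol)
        stop("integration failure: %s = %g left the state box at step %.0f",
             nm[i], y[i], (double)step);
      y[i] = 0.0;
    } else if (y[i] > hi[i]) {
      if (y[i] > hi[i] + tol)
        stop("integration failure: %s = %g left the state box at step %.0f",
             nm[i], y[i], (double)step);
      y[i] = hi[i];
    }
  }
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector y0, NumericVector pars, double dt, double n_steps,
              int store_every, bool noisy, double noise_mean, double noise_sd,
              double clip_tol) {
  if (y0.size() != NSTATE) stop("state vector must have 7 components");
  if (pars.size() != P_NPAR) stop("parameter vector has wrong length");
  if (dt <= 0) stop("dt must be positive");
  if (store_every < 1) stop("store_every must be >= 1");

  const double *p = REAL(pars);
  const R_xlen_t ns = (R_xlen_t)n_steps;
  const R_xlen_t nstore = ns / store_every + 1;

  NumericMatrix states(nstore, NSTATE);
  NumericVector tgrid(nstore);
  NumericVector lo(NSTATE, R_PosInf), hi(NSTATE, R_NegInf);

  double y[NSTATE], ynext[NSTATE], xi[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  RNGScope scope;  // draws come from R's RNG: seeding happens in R

  R_xlen_t istore = 0;
  for (int i = 0; i < NSTATE; ++i) {
    states(0, i) = y[i];
    lo[i] = std::min((double)lo[i], y[i]);
    hi[i] = std::max((double)hi[i], y[i]);
  }
  tgrid[0] = 0.0;
  ++istore;

  for (R_xlen_t s = 1; s <= ns; ++s) {
    if (noisy) {  // one draw per population per step, order W, N, R
      xi[0] = ::Rf_rnorm(noise_mean, noise_sd);
      xi[1] = ::Rf_rnorm(noise_mean, noise_sd);
      xi[2] = ::Rf_rnorm(noise_mean, noise_sd);
    }
    rk4(y, p, xi, dt, ynext);
    clip_box(ynext, p, clip_tol, s);
    for (int i = 0; i < NSTATE; ++i) {
      y[i] = ynext[i];
      if (y[i] < lo[i]) lo[i] = y[i];
      if (y[i] > hi[i]) hi[i] = y[i];
    }
    if (s % store_every == 0) {
      for (int i = 0; i < NSTATE; ++i) states(istore, i) = y[i];
      tgrid[istore] = s * dt;
      ++istore;
    }
    if ((s & 0xFFFFF) == 0) checkUserInterrupt();
  }

  colnames(states) = CharacterVector::create("F_W", "F_N", "F_R",
                                             "C_W", "C_N", "C_R", "H");
  return List::create(_["time"] = tgrid, _["states"] = states,
                      _["state_min"] = lo, _["state_max"] = hi,
                      _["n_steps"] = (double)ns);
}

// Single RK4 step with explicit noise draws; used to cross-check the compiled
// right-hand side against the R reference implementation.
// [[Rcpp::export(name = ".rk4_step_core")]]
NumericVector rk4_step_core(NumericVector y0, NumericVector pars, double dt,
                            NumericVector xi) {
  if (y0.size() != NSTATE) stop("state vector must have 7 components");
  if (pars.size() != P_NPAR) stop("parameter vector has wrong length");
  if (xi.size() != 3) stop("xi must have 3 components");
  double y[NSTATE], out[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];
  rk4(y, REAL(pars), REAL(xi), dt, out);
  NumericVector res(NSTATE);
  for (int i = 0; i < NSTATE; ++i) res[i] = out[i];
  res.names() = CharacterVector::create("F_W", "F_N", "F_R",
                                        "C_W", "C_N", "C_R", "H");
  return res;
}
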