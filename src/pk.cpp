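// Two-compartment trastuzumab model with parallel linear and Michaelis-Menten
// elimination and first-order absorption from a subcutaneous depot.
// States: A[0] depot (mg), A[1] central (mg), A[2] peripheral (mg),
// A[3] cumulative AUC of central concentration (mg*day/L).
// Parameter vector layout (shared with R): F, Ka, CL, Vmax, Km, Vc, Q, Vp.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void pk_deriv(const double* A, const double* p, double rate,
                            double* dA) {
  // p: Ka, CL, Vmax, Km, Vc, Q, Vp (F is applied to dose amounts, not here)
  const double Ka = p[0], CL = p[1], Vmax = p[2], Km = p[3], Vc = p[4],
               Q = p[5], Vp = p[6];
  const double C = A[1] / Vc;
  dA[0] = -Ka * A[0];
  dA[1] = Ka * A[0] + rate - (CL / Vc) * A[1] - Vmax * C / (Km + C) -
          (Q / Vc) * A[1] + (Q / Vp) * A[2];
  dA[2] = (Q / Vc) * A[1] - (Q / Vp) * A[2];
  dA[3] = C;
}

// Dormand-Prince 5(4) embedded pair.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order weights (for the error estimate, includes k7 = f(y_new))
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate from t0 to t1 with constant infusion rate; A updated in place.
// Returns false when the step budget is exhausted or the state leaves the
// representable range (callers decide whether that is an error or simply an
// unusable parameter proposal).
static bool rk45_segment(double* A, const double* p, double rate, double t0,
                         double t1, double rtol, double atol, double* h_carry) {
  const int ns = 4;
  double t = t0;
  double h = *h_carry;
  const double span = t1 - t0;
  if (span <= 0) return true;
  if (h <= 0 || h > span) h = span;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], ytmp[4], y5[4];
  pk_deriv(A, p, rate, k1);
  int iter = 0;
  while (t < t1 - 1e-13 * (1.0 + std::fabs(t1))) {
    if (++iter > 20000) return false;
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < ns; ++i) ytmp[i] = A[i] + h * a21 * k1[i];
    pk_deriv(ytmp, p, rate, k2);
    for (int i = 0; i < ns; ++i)
      ytmp[i] = A[i] + h * (a31 * k1[i] + a32 * k2[i]);
    pk_deriv(ytmp, p, rate, k3);
    for (int i = 0; i < ns; ++i)
      ytmp[i] = A[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    pk_deriv(ytmp, p, rate, k4);
    for (int i = 0; i < ns; ++i)
      ytmp[i] = A[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    pk_deriv(ytmp, p, rate, k5);
    for (int i = 0; i < ns; ++i)
      ytmp[i] = A[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    pk_deriv(ytmp, p, rate, k6);
    for (int i = 0; i < ns; ++i)
      y5[i] = A[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    pk_deriv(y5, p, rate, k7);
    double err = 0.0;
    for (int i = 0; i < ns; ++i) {
      double y4 = A[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(A[i]), std::fabs(y5[i]));
      double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / ns);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < ns; ++i) { A[i] = y5[i]; k1[i] = k7[i]; }  // FSAL
      double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
    }
  }
  *h_carry = h;
  return true;
}

// Core multi-dose simulation. Doses are (time, amount-into-depot) boluses and
// (start, duration, amount) zero-order infusions into the central compartment.
// Output times must be sorted ascending; returns central conc and cumulative
// AUC at each output time (pre-dose convention: outputs coinciding with a
// bolus time are evaluated before the bolus is applied only if `predose`).
static bool simulate_core(const double* p7, const arma::vec& bt,
                          const arma::vec& ba, const arma::vec& is,
                          const arma::vec& idur, const arma::vec& ia,
                          const arma::vec& times, double rtol, double atol,
                          bool predose, arma::vec& conc, arma::vec& auc,
                          arma::mat* states) {
  const double Vc = p7[4];
  std::vector<double> brk;
  brk.push_back(0.0);
  for (arma::uword i = 0; i < bt.n_elem; ++i) brk.push_back(bt[i]);
  for (arma::uword i = 0; i < is.n_elem; ++i) {
    brk.push_back(is[i]);
    brk.push_back(is[i] + idur[i]);
  }
  for (arma::uword i = 0; i < times.n_elem; ++i) brk.push_back(times[i]);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            brk.end());
  double A[4] = {0, 0, 0, 0};
  double h_carry = 0.0;
  arma::uword iout = 0;
  const double eps = 1e-12;
  auto record = [&](double tcur) {
    while (iout < times.n_elem && times[iout] <= tcur + eps) {
      conc[iout] = A[1] / Vc;
      auc[iout] = A[3];
      if (states) {
        (*states)(iout, 0) = A[0];
        (*states)(iout, 1) = A[1];
        (*states)(iout, 2) = A[2];
        (*states)(iout, 3) = A[3];
      }
      ++iout;
    }
  };
  // outputs at t <= first breakpoint start (t=0 before any dosing)
  for (size_t s = 0; s + 1 <= brk.size(); ++s) {
    double t0 = brk[s];
    // record outputs at t0 (pre-dose)
    if (predose) record(t0);
    // apply boluses at t0
    for (arma::uword k = 0; k < bt.n_elem; ++k)
      if (std::fabs(bt[k] - t0) < 1e-12) A[0] += ba[k];
    if (!predose) record(t0);
    if (s + 1 == brk.size()) break;
    double t1 = brk[s + 1];
    double rate = 0.0;
    double tm = 0.5 * (t0 + t1);
    for (arma::uword k = 0; k < is.n_elem; ++k)
      if (tm > is[k] - eps && tm < is[k] + idur[k] + eps) rate += ia[k] / idur[k];
    if (!rk45_segment(A, p7, rate, t0, t1, rtol, atol, &h_carry))
      return false;
  }
  record(brk.back() + 1.0);  // flush any outputs exactly at the end
  return true;
}

// [[Rcpp::export]]
List pk_solve_cpp(NumericVector params, NumericVector bolus_time,
                  NumericVector bolus_amt, NumericVector inf_start,
                  NumericVector inf_dur, NumericVector inf_amt,
                  NumericVector times, double rtol, double atol,
                  bool predose, bool full_state) {
  // params: Ka, CL, Vmax, Km, Vc, Q, Vp (F already folded into bolus_amt)
  double p7[7];
  for (int i = 0; i < 7; ++i) p7[i] = params[i];
  arma::vec bt(bolus_time.begin(), bolus_time.size());
  arma::vec ba(bolus_amt.begin(), bolus_amt.size());
  arma::vec is(inf_start.begin(), inf_start.size());
  arma::vec idur(inf_dur.begin(), inf_dur.size());
  arma::vec ia(inf_amt.begin(), inf_amt.size());
  arma::vec tv(times.begin(), times.size());
  arma::vec conc(tv.n_elem, arma::fill::zeros), auc(tv.n_elem, arma::fill::zeros);
  arma::mat st;
  arma::mat* stp = nullptr;
  if (full_state) { st.set_size(tv.n_elem, 4); stp = &st; }
  if (!simulate_core(p7, bt, ba, is, idur, ia, tv, rtol, atol, predose, conc,
                     auc, stp))
    stop("ODE solver failed (step budget exhausted or non-finite state)");
  List out = List::create(Named("conc") = wrap(conc), Named("auc") = wrap(auc));
  if (full_state) out["state"] = wrap(st);
  return out;
}

// ---------------------------------------------------------------------------
// FOCEI engine
// ---------------------------------------------------------------------------
// Random-effect layout (diagonal Omega): eta on F, CL, Vc, Vp (log-normal).
// Subject data arrive flattened with pointer offsets.
//
// The inner (conditional-mode) optimization uses analytic forward
// sensitivities of the ODE system with respect to the four random effects:
// the base 3-state system is augmented with d(state)/d(eta_k) columns, so a
// single adaptive integration yields both predictions and the exact
// linearization Jacobian. The conditional objective is then minimized by a
// damped Gauss-Newton iteration.

struct SubjData {
  arma::vec obs_t, y;
  arma::vec dose_t, dose_amt, dose_dur;
  arma::ivec dose_route;  // 0 = SC depot bolus, 1 = IV infusion
  arma::vec theta;        // F, Ka, CL, Vmax, Km, Vc, Q, Vp after covariates
};

// Predict concentrations at obs times given eta (length 4: F, CL, Vc, Vp).
static arma::vec predict_subject(const SubjData& d, const arma::vec& eta,
                                 double rtol, double atol) {
  double F = d.theta[0] * std::exp(eta[0]);
  double p7[7] = {d.theta[1], d.theta[2] * std::exp(eta[1]), d.theta[3],
                  d.theta[4], d.theta[5] * std::exp(eta[2]), d.theta[6],
                  d.theta[7] * std::exp(eta[3])};
  std::vector<double> bt, ba, is, idur, ia;
  for (arma::uword k = 0; k < d.dose_t.n_elem; ++k) {
    if (d.dose_route[k] == 0) {
      bt.push_back(d.dose_t[k]);
      ba.push_back(F * d.dose_amt[k]);
    } else {
      is.push_back(d.dose_t[k]);
      idur.push_back(std::max(d.dose_dur[k], 1e-6));
      ia.push_back(d.dose_amt[k]);
    }
  }
  arma::vec conc(d.obs_t.n_elem, arma::fill::zeros),
      auc(d.obs_t.n_elem, arma::fill::zeros);
  if (!simulate_core(p7, arma::vec(bt), arma::vec(ba), arma::vec(is),
                     arma::vec(idur), arma::vec(ia), d.obs_t, rtol, atol,
                     false, conc, auc, nullptr))
    conc.fill(arma::datum::nan);
  return conc;
}

// Augmented RHS: base 3 states plus a 3-vector sensitivity block per active
// random effect (d state / d eta_k, with parameters p_k = base * exp(eta_k)).
struct SensSystem {
  double Ka, CL, Vmax, Km, Vc, Q, Vp;  // individual values
  const arma::uvec* act;               // active eta indices (0 F,1 CL,2 Vc,3 Vp)
  void rhs(const arma::vec& y, double rate, arma::vec& dy) const {
    const double A0 = y[0], A1 = y[1], A2 = y[2];
    const double C = A1 / Vc;
    const double den = Km + C;
    const double MM = Vmax * C / den;
    const double MMp = Vmax * Km / (den * den);  // dMM/dC
    dy[0] = -Ka * A0;
    dy[1] = Ka * A0 + rate - (CL / Vc) * A1 - MM - (Q / Vc) * A1 +
            (Q / Vp) * A2;
    dy[2] = (Q / Vc) * A1 - (Q / Vp) * A2;
    const double J11 = -(CL + Q + MMp) / Vc;
    for (arma::uword j = 0; j < act->n_elem; ++j) {
      const double* S = y.memptr() + 3 + 3 * j;
      double* dS = dy.memptr() + 3 + 3 * j;
      dS[0] = -Ka * S[0];
      dS[1] = Ka * S[0] + J11 * S[1] + (Q / Vp) * S[2];
      dS[2] = (Q / Vc) * S[1] - (Q / Vp) * S[2];
      switch ((*act)[j]) {
        case 1:  // eta on CL
          dS[1] += -CL * A1 / Vc;
          break;
        case 2:  // eta on Vc
          dS[1] += CL * A1 / Vc + MMp * C + Q * A1 / Vc;
          dS[2] += -Q * A1 / Vc;
          break;
        case 3:  // eta on Vp
          dS[1] += -Q * A2 / Vp;
          dS[2] += Q * A2 / Vp;
          break;
        default: break;  // eta on F acts through dose events only
      }
    }
  }
};

// Adaptive Dormand-Prince on the augmented system over one constant-rate
// segment.
static bool rk45_sens_segment(arma::vec& y, const SensSystem& sys, double rate,
                              double t0, double t1, double rtol, double atol,
                              double* h_carry) {
  const arma::uword ns = y.n_elem;
  double t = t0;
  double h = *h_carry;
  const double span = t1 - t0;
  if (span <= 0) return true;
  if (h <= 0 || h > span) h = span;
  arma::vec k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns), ytmp(ns),
      y5(ns);
  sys.rhs(y, rate, k1);
  int iter = 0;
  while (t < t1 - 1e-13 * (1.0 + std::fabs(t1))) {
    if (++iter > 20000) return false;
    if (t + h > t1) h = t1 - t;
    ytmp = y + h * a21 * k1;
    sys.rhs(ytmp, rate, k2);
    ytmp = y + h * (a31 * k1 + a32 * k2);
    sys.rhs(ytmp, rate, k3);
    ytmp = y + h * (a41 * k1 + a42 * k2 + a43 * k3);
    sys.rhs(ytmp, rate, k4);
    ytmp = y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
    sys.rhs(ytmp, rate, k5);
    ytmp = y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    sys.rhs(ytmp, rate, k6);
    y5 = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    sys.rhs(y5, rate, k7);
    double err = 0.0;
    for (arma::uword i = 0; i < ns; ++i) {
      double y4i = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                               e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double dd = (y5[i] - y4i) / sc;
      err += dd * dd;
    }
    err = std::sqrt(err / ns);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      y = y5;
      k1 = k7;
      double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
    }
  }
  *h_carry = h;
  return true;
}

// One integration pass yielding predictions f and the exact Jacobian
// G = df/deta (active columns filled, others zero).
static void solve_sens(const SubjData& d, const arma::vec& eta,
                       const arma::uvec& act, double rtol, double atol,
                       arma::vec& f, arma::mat& G) {
  const arma::uword nobs = d.obs_t.n_elem;
  const arma::uword nact = act.n_elem;
  f.zeros(nobs);
  G.zeros(nobs, 4);
  SensSystem sys;
  const double F_ind = d.theta[0] * std::exp(eta[0]);
  sys.Ka = d.theta[1];
  sys.CL = d.theta[2] * std::exp(eta[1]);
  sys.Vmax = d.theta[3];
  sys.Km = d.theta[4];
  sys.Vc = d.theta[5] * std::exp(eta[2]);
  sys.Q = d.theta[6];
  sys.Vp = d.theta[7] * std::exp(eta[3]);
  sys.act = &act;
  // breakpoints: dose times, infusion ends, observation times
  std::vector<double> brk;
  brk.push_back(0.0);
  for (arma::uword k = 0; k < d.dose_t.n_elem; ++k) {
    brk.push_back(d.dose_t[k]);
    if (d.dose_route[k] == 1)
      brk.push_back(d.dose_t[k] + std::max(d.dose_dur[k], 1e-6));
  }
  for (arma::uword j = 0; j < nobs; ++j) brk.push_back(d.obs_t[j]);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            brk.end());
  arma::vec y(3 + 3 * nact, arma::fill::zeros);
  double h_carry = 0.0;
  arma::uword iout = 0;
  const double eps = 1e-12;
  auto record = [&](double tcur) {
    while (iout < nobs && d.obs_t[iout] <= tcur + eps) {
      const double A1 = y[1];
      f[iout] = A1 / sys.Vc;
      for (arma::uword j = 0; j < nact; ++j) {
        double g = y[3 + 3 * j + 1] / sys.Vc;
        if (act[j] == 2) g -= A1 / sys.Vc;  // explicit Vc in C = A1/Vc
        G(iout, act[j]) = g;
      }
      ++iout;
    }
  };
  for (size_t s = 0; s < brk.size(); ++s) {
    double t0 = brk[s];
    // depot boluses at t0 (after recording would be equivalent: the bolus
    // does not change the central amount)
    for (arma::uword k = 0; k < d.dose_t.n_elem; ++k) {
      if (d.dose_route[k] == 0 && std::fabs(d.dose_t[k] - t0) < 1e-12) {
        y[0] += F_ind * d.dose_amt[k];
        for (arma::uword j = 0; j < nact; ++j)
          if (act[j] == 0) y[3 + 3 * j] += F_ind * d.dose_amt[k];
      }
    }
    record(t0);
    if (s + 1 == brk.size()) break;
    double t1 = brk[s + 1];
    double rate = 0.0;
    double tm = 0.5 * (t0 + t1);
    for (arma::uword k = 0; k < d.dose_t.n_elem; ++k) {
      if (d.dose_route[k] == 1) {
        double dur = std::max(d.dose_dur[k], 1e-6);
        if (tm > d.dose_t[k] - eps && tm < d.dose_t[k] + dur + eps)
          rate += d.dose_amt[k] / dur;
      }
    }
    if (!rk45_sens_segment(y, sys, rate, t0, t1, rtol, atol, &h_carry)) {
      f.fill(arma::datum::nan);
      return;
    }
  }
  record(brk.back() + 1.0);
}

// Conditional -2 log joint (up to the constant log|2*pi*Omega|):
// sum_j [log(2*pi*v_j) + (y_j - f_j)^2 / v_j] + sum_k eta_k^2 / omega_k^2
static double cond_obj_value(const arma::vec& y, const arma::vec& f,
                             const arma::vec& eta, const arma::uvec& act,
                             const arma::vec& omega, double sp, double sa) {
  double val = 0.0;
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    double v = sp * sp * f[j] * f[j] + sa * sa;
    if (v <= 0 || !std::isfinite(f[j])) return 1e30;
    double r = y[j] - f[j];
    val += std::log(2.0 * M_PI * v) + r * r / v;
  }
  for (arma::uword k = 0; k < act.n_elem; ++k) {
    arma::uword a = act[k];
    val += eta[a] * eta[a] / (omega[a] * omega[a]);
  }
  return val;
}

// Damped Gauss-Newton minimization of the conditional objective. Cheap
// 4-state solves are used for start selection and line-search rejection;
// the augmented sensitivity solve runs once per accepted iterate (and
// provides the final linearization for the marginal likelihood).
static arma::vec inner_optimize(const SubjData& d, const arma::uvec& act,
                                const arma::vec& omega, double sp, double sa,
                                double rtol, double atol, arma::vec eta,
                                double gtol, int maxit, arma::vec& f,
                                arma::mat& G) {
  const arma::uword m = act.n_elem;
  if (m == 0) {
    solve_sens(d, eta, act, rtol, atol, f, G);
    return eta;
  }
  auto hfun = [&](const arma::vec& e) {
    arma::vec fp = predict_subject(d, e, rtol, atol);
    return cond_obj_value(d.y, fp, e, act, omega, sp, sa);
  };
  solve_sens(d, eta, act, rtol, atol, f, G);
  double hval = cond_obj_value(d.y, f, eta, act, omega, sp, sa);
  if (hval >= 1e30 && arma::norm(eta, "inf") > 0) {
    // restart from zero when the warm start is unusable
    eta.zeros();
    solve_sens(d, eta, act, rtol, atol, f, G);
    hval = cond_obj_value(d.y, f, eta, act, omega, sp, sa);
  }
  bool fresh = true;  // do f,G correspond to the current eta?
  for (int it = 0; it < maxit; ++it) {
    if (!fresh) {
      solve_sens(d, eta, act, rtol, atol, f, G);
      fresh = true;
    }
    if (!f.is_finite()) break;
    arma::vec grad(m, arma::fill::zeros);
    arma::mat H(m, m, arma::fill::zeros);
    for (arma::uword j = 0; j < f.n_elem; ++j) {
      const double v = sp * sp * f[j] * f[j] + sa * sa;
      const double r = d.y[j] - f[j];
      arma::vec g(m);
      for (arma::uword k = 0; k < m; ++k) g[k] = G(j, act[k]);
      const arma::vec vp = 2.0 * sp * sp * f[j] * g;
      grad += vp / v - 2.0 * r * g / v - (r * r / (v * v)) * vp;
      // Fisher information of N(f, v) for -2LL: mean and variance terms
      H += (2.0 / v) * (g * g.t()) + (vp * vp.t()) / (v * v);
    }
    for (arma::uword k = 0; k < m; ++k) {
      const double w2 = omega[act[k]] * omega[act[k]];
      grad[k] += 2.0 * eta[act[k]] / w2;
      H(k, k) += 2.0 / w2;
    }
    if (!grad.is_finite()) break;
    if (arma::norm(grad, "inf") < gtol) break;
    // ridge-regularized Gauss-Newton step
    const double ridge = 1e-10 * arma::trace(H) + 1e-12;
    for (arma::uword k = 0; k < m; ++k) H(k, k) += ridge;
    arma::vec step;
    if (!arma::solve(step, H, -grad, arma::solve_opts::no_approx))
      step = -grad / arma::norm(grad, "inf");
    double lam = 1.0;
    bool ok = false;
    for (int ls = 0; ls < 25; ++ls) {
      arma::vec eta_new = eta;
      for (arma::uword k = 0; k < m; ++k) {
        double x = eta[act[k]] + lam * step[k];
        eta_new[act[k]] = std::min(6.0, std::max(-6.0, x));
      }
      double h_new = hfun(eta_new);
      if (h_new < hval - 1e-12) {
        eta = eta_new;
        hval = h_new;
        fresh = false;
        ok = true;
        break;
      }
      lam *= 0.5;
    }
    if (!ok) break;
  }
  if (!fresh) solve_sens(d, eta, act, rtol, atol, f, G);
  return eta;
}

static std::vector<SubjData> build_subjects(const List& dat) {
  IntegerVector obs_ptr = dat["obs_ptr"], dose_ptr = dat["dose_ptr"],
                route = dat["dose_route"];
  NumericVector obs_t = dat["obs_time"], y = dat["y"], dt = dat["dose_time"],
                da = dat["dose_amt"], dd = dat["dose_dur"];
  NumericMatrix th = dat["theta"];
  int n = obs_ptr.size() - 1;
  std::vector<SubjData> subj(n);
  for (int i = 0; i < n; ++i) {
    int o0 = obs_ptr[i], o1 = obs_ptr[i + 1];
    int d0 = dose_ptr[i], d1 = dose_ptr[i + 1];
    subj[i].obs_t = arma::vec(o1 - o0);
    subj[i].y = arma::vec(o1 - o0);
    for (int j = o0; j < o1; ++j) {
      subj[i].obs_t[j - o0] = obs_t[j];
      subj[i].y[j - o0] = y[j];
    }
    subj[i].dose_t = arma::vec(d1 - d0);
    subj[i].dose_amt = arma::vec(d1 - d0);
    subj[i].dose_dur = arma::vec(d1 - d0);
    subj[i].dose_route = arma::ivec(d1 - d0);
    for (int j = d0; j < d1; ++j) {
      subj[i].dose_t[j - d0] = dt[j];
      subj[i].dose_amt[j - d0] = da[j];
      subj[i].dose_dur[j - d0] = dd[j];
      subj[i].dose_route[j - d0] = route[j];
    }
    subj[i].theta = arma::vec(8);
    for (int k = 0; k < 8; ++k) subj[i].theta[k] = th(i, k);
  }
  return subj;
}

// Full-population FOCEI objective. `dat` is the flattened workspace built in R.
// Returns OFV, per-subject contributions and conditional modes.
// [[Rcpp::export]]
List focei_ofv_cpp(List dat, NumericVector omega, double sigma_prop,
                   double sigma_add, NumericMatrix eta_start, double rtol,
                   double atol, double gtol, int maxit) {
  std::vector<SubjData> subj = build_subjects(dat);
  const int n = (int)subj.size();
  arma::vec om(omega.begin(), 4);
  arma::vec ofv_i(n, arma::fill::zeros);
  arma::mat eta_hat(n, 4, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const SubjData& d = subj[i];
    // bioavailability carries no information for subjects without SC doses;
    // their eta_F stays at its conditional mode 0
    bool has_sc = false;
    for (arma::uword k = 0; k < d.dose_route.n_elem; ++k)
      if (d.dose_route[k] == 0) has_sc = true;
    std::vector<arma::uword> actv;
    for (int k = 0; k < 4; ++k)
      if (om[k] > 0 && (k != 0 || has_sc)) actv.push_back(k);
    arma::uvec act(actv);
    arma::vec e0(4, arma::fill::zeros);
    for (int k = 0; k < 4; ++k) e0[k] = eta_start(i, k);
    arma::vec f;
    arma::mat G;
    arma::vec eh = inner_optimize(d, act, om, sigma_prop, sigma_add, rtol, atol,
                                  e0, gtol, maxit, f, G);
    if (!f.is_finite())
      stop("FOCEI: ODE integration failed for subject %d", i + 1);
    const arma::uword nobs = f.n_elem;
    arma::vec v(nobs);
    for (arma::uword j = 0; j < nobs; ++j)
      v[j] = sigma_prop * sigma_prop * f[j] * f[j] + sigma_add * sigma_add;
    arma::mat V = arma::diagmat(v);
    for (int k = 0; k < 4; ++k)
      if (om[k] > 0) V += (om[k] * om[k]) * (G.col(k) * G.col(k).t());
    arma::vec r = d.y - f + G * eh;
    arma::mat L;
    if (!arma::chol(L, V, "lower"))
      stop("FOCEI: marginal covariance not positive definite for subject %d", i + 1);
    arma::vec z = arma::solve(arma::trimatl(L), r);
    double logdet = 0.0;
    for (arma::uword j = 0; j < nobs; ++j) logdet += 2.0 * std::log(L(j, j));
    ofv_i[i] = nobs * std::log(2.0 * M_PI) + logdet + arma::dot(z, z);
    eta_hat.row(i) = eh.t();
  }
  return List::create(Named("ofv") = arma::accu(ofv_i),
                      Named("ofv_i") = wrap(ofv_i),
                      Named("eta_hat") = wrap(eta_hat));
}

// Linearization pieces at a supplied eta (eta = 0 rows gives the FO/WRES
// linearization; eta = conditional modes gives the FOCE/CWRES one).
// [[Rcpp::export]]
List focei_linearize_cpp(List dat, NumericVector omega, double sigma_prop,
                         double sigma_add, NumericMatrix eta, double rtol,
                         double atol) {
  std::vector<SubjData> subj = build_subjects(dat);
  const int n = (int)subj.size();
  arma::vec om(omega.begin(), 4);
  std::vector<arma::uword> actv;
  for (int k = 0; k < 4; ++k)
    if (om[k] > 0) actv.push_back(k);
  arma::uvec act(actv);
  List out(n);
  for (int i = 0; i < n; ++i) {
    const SubjData& d = subj[i];
    arma::vec e(4);
    for (int k = 0; k < 4; ++k) e[k] = eta(i, k);
    arma::vec f;
    arma::mat G;
    solve_sens(d, e, act, rtol, atol, f, G);
    out[i] = List::create(Named("f") = wrap(f), Named("G") = wrap(G));
  }
  return out;
}

// Batch profile simulation for many subjects (population simulation / VPC):
// one call per dataset rather than per subject keeps R overhead off the loop.
// [[Rcpp::export]]
List pk_predict_batch_cpp(List dat, NumericMatrix eta, double rtol,
                          double atol) {
  std::vector<SubjData> subj = build_subjects(dat);
  const int n = (int)subj.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    arma::vec e(4);
    for (int k = 0; k < 4; ++k) e[k] = eta(i, k);
    out[i] = wrap(predict_subject(subj[i], e, rtol, atol));
  }
  return out;
}
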