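#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Lumped-parameter circuit of the perfused eye.
// States: x1 = P_S (across C_S), x2 = pressure across C_W2 (series wall
// element adjacent to the eye node), x3 = pressure across C_W1 (inner wall
// node, drained by R_W).  P_E = x2 + x3.  With R_W == 0 the inner node is
// clamped and the model reduces to two states (x3 == 0).
struct Model {
  double Pbar, RT, RW, CW1, CW2, RC, CS;
  bool elastic; // RW == 0

  inline void deriv(const double* x, double Fin, double* dx) const {
    double PE = x[1] + x[2];
    double iRC = (x[0] - PE) / RC;
    double iT = (PE - Pbar) / RT;
    double iw = iRC - iT;
    dx[0] = (Fin - iRC) / CS;
    if (elastic) {
      dx[1] = iw / CW2;
      dx[2] = 0.0;
    } else {
      dx[1] = iw / CW2;
      dx[2] = (iw - x[2] / RW) / CW1;
    }
  }
};

enum Mode { CF = 0, CPG = 1, CPP_DIGITAL = 2, CPP_ANALOG = 3 };

// [[Rcpp::export]]
List sim_perfusion_cpp(int mode, NumericVector input, NumericVector noise,
                       double dt_min, int n_sub, List eye, List sys,
                       double RS, double K, int delay_steps, int fb_filter_steps,
                       double flow_min, double flow_max,
                       NumericVector x0, NumericVector fb_warm) {
  int n = input.size(); // number of recorded samples (incl. t = 0)
  Model m;
  m.Pbar = eye["resting_iop"];
  m.RT = eye["trabecular_resistance"];
  m.RW = eye["wall_resistance"];
  m.CW1 = eye["wall_compliance_1"];
  m.CW2 = eye["wall_compliance_2"];
  m.RC = sys["cannula_resistance"];
  m.CS = sys["system_compliance"];
  m.elastic = (m.RW <= 0.0);

  NumericVector ps(n), fs(n), pe(n), fe(n);
  NumericMatrix xs(n, 3);
  double x[3] = { x0[0], x0[1], x0[2] };
  if (m.elastic) x[2] = 0.0;

  // measured-pressure history for the digital controller (delay + smoothing)
  int nwarm = fb_warm.size();
  std::vector<double> meas(nwarm + n);
  for (int i = 0; i < nwarm; ++i) meas[i] = fb_warm[i];

  double cmd = 0.0; // held source flow for the digital pump
  double h = dt_min / n_sub;

  for (int k = 0; k < n; ++k) {
    double p_meas = x[0] + noise[k];
    meas[nwarm + k] = p_meas;
    ps[k] = p_meas;
    xs(k, 0) = x[0]; xs(k, 1) = x[1]; xs(k, 2) = x[2];
    double PE = x[1] + x[2];
    pe[k] = PE;
    fe[k] = (x[0] - PE) / m.RC;

    // controller output at sample k
    if (mode == CF) {
      cmd = input[k];
    } else if (mode == CPG) {
      cmd = (input[k] - p_meas) / RS;
    } else if (mode == CPP_DIGITAL) {
      // feedback signal: trailing moving average over fb_filter_steps
      // samples (growing window while fewer are available), read with a
      // delay of delay_steps update intervals
      int idx = nwarm + k - delay_steps;
      if (idx < 0) idx = 0;
      double fb;
      if (fb_filter_steps > 1) {
        int lo = idx - fb_filter_steps + 1;
        if (lo < 0) lo = 0;
        double s = 0.0;
        for (int j = lo; j <= idx; ++j) s += meas[j];
        fb = s / (idx - lo + 1);
      } else {
        fb = meas[idx];
      }
      cmd = K * (input[k] - fb);
    } else { // CPP_ANALOG: evaluated continuously inside the stages
      cmd = K * (input[k] - x[0]);
    }
    if (cmd < flow_min) cmd = flow_min;
    if (cmd > flow_max) cmd = flow_max;
    fs[k] = cmd;

    if (k == n - 1) break; // final sample recorded, no step beyond

    // integrate over [k, k+1)
    for (int s = 0; s < n_sub; ++s) {
      double k1[3], k2[3], k3[3], k4[3], xt[3];
      double u = input[k], nz = noise[k];
      // stage-wise source flow
      auto fin = [&](const double* xs) -> double {
        double f;
        switch (mode) {
        case CF: f = u; break;
        case CPG: f = (u - (xs[0] + nz)) / RS; break;
        case CPP_ANALOG: f = K * (u - xs[0]); break;
        default: f = cmd; // digital pump: zero-order hold
        }
        if (f < flow_min) f = flow_min;
        if (f > flow_max) f = flow_max;
        return f;
      };
      m.deriv(x, fin(x), k1);
      for (int i = 0; i < 3; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
      m.deriv(xt, fin(xt), k2);
      for (int i = 0; i < 3; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
      m.deriv(xt, fin(xt), k3);
      for (int i = 0; i < 3; ++i) xt[i] = x[i] + h * k3[i];
      m.deriv(xt, fin(xt), k4);
      for (int i = 0; i < 3; ++i)
        x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    if (!std::isfinite(x[0]) || !std::isfinite(x[1]) || !std::isfinite(x[2]))
      stop("simulation diverged (non-finite state) at t = %.3f min",
           (k + 1) * dt_min);
  }

  return List::create(_["p_s"] = ps, _["f_s"] = fs, _["p_e"] = pe,
                      _["f_e"] = fe, _["states"] = xs,
                      _["state"] = NumericVector::create(x[0], x[1], x[2]));
}

// Trailing-window range (max - min) over w samples, right-aligned;
// the first w-1 entries are NA.  O(n) via monotonic deques.
// [[Rcpp::export]]
NumericVector roll_range_cpp(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  std::deque<int> qmax, qmin;
  for (int i = 0; i < n; ++i) {
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmax.push_back(i);
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    qmin.push_back(i);
    if (qmax.front() <= i - w) qmax.pop_front();
    if (qmin.front() <= i - w) qmin.pop_front();
    if (i >= w - 1) out[i] = x[qmax.front()] - x[qmin.front()];
  }
  return out;
}

// ---- recursive exponential regression ------------------------------------
// Model: PS*(t) = A (1 - exp(-t/tau)) + B,  FS*(t) = C exp(-t/tau) + D,
// shared tau, flow residuals scaled by wf.  For fixed tau both channels are
// linear least-squares problems solved from running sums; tau is profiled
// by golden-section search on log(tau), warm-started from the previous fit.

// profile SSE at a given tau over points t[0..n-1]
static double profile_sse(const double* t, const double* p, const double* f,
                          int n, double tau, double wf, double* coef) {
  double Su = 0, Suu = 0, Spu = 0, Sfu = 0, Sp = 0, Sf = 0;
  for (int i = 0; i < n; ++i) {
    double u = std::exp(-t[i] / tau);
    Su += u; Suu += u * u; Spu += p[i] * u; Sfu += f[i] * u;
    Sp += p[i]; Sf += f[i];
  }
  // pressure channel, regressor v = 1 - u
  double Sv = n - Su, Svv = n - 2 * Su + Suu, Spv = Sp - Spu;
  double detp = n * Svv - Sv * Sv;
  double A, B, C, D;
  bool ok = std::fabs(detp) > 1e-9 * n * n;
  if (ok) {
    A = (n * Spv - Sv * Sp) / detp;
    B = (Sp - A * Sv) / n;
  } else { A = 0; B = Sp / n; }
  double detf = n * Suu - Su * Su;
  if (std::fabs(detf) > 1e-9 * n * n) {
    C = (n * Sfu - Su * Sf) / detf;
    D = (Sf - C * Su) / n;
  } else { C = 0; D = Sf / n; }
  coef[0] = A; coef[1] = B; coef[2] = C; coef[3] = D;
  // tau is unidentifiable when both exponential amplitudes vanish
  coef[4] = (ok && (std::fabs(A) > 1e-8 || std::fabs(C) > 1e-8)) ? 1.0 : 0.0;
  double sse = 0;
  for (int i = 0; i < n; ++i) {
    double u = std::exp(-t[i] / tau);
    double rp = p[i] - (A * (1 - u) + B);
    double rf = wf * (f[i] - (C * u + D));
    sse += rp * rp + rf * rf;
  }
  return sse;
}

static double golden_tau(const double* t, const double* p, const double* f,
                         int n, double lo, double hi, double wf,
                         double* coef, double* sse_out) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double cf[5];
  double fc = profile_sse(t, p, f, n, std::exp(c), wf, cf);
  double fd = profile_sse(t, p, f, n, std::exp(d), wf, cf);
  for (int it = 0; it < 40 && (b - a) > 1e-3; ++it) {
    if (fc < fd) { b = d; d = c; fd = fc; c = b - gr * (b - a);
      fc = profile_sse(t, p, f, n, std::exp(c), wf, cf); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a);
      fd = profile_sse(t, p, f, n, std::exp(d), wf, cf); }
  }
  double tau = std::exp(0.5 * (a + b));
  *sse_out = profile_sse(t, p, f, n, tau, wf, coef);
  return tau;
}

// [[Rcpp::export]]
List recursive_fit_path_cpp(NumericVector t, NumericVector p, NumericVector f,
                            double fit_start_min, double update_min,
                            double wf, double tau_lo, double tau_hi) {
  int n = t.size();
  std::vector<int> upd; // sample index of each refit
  for (int i = 0; i < n; ++i) {
    if (t[i] + 1e-9 >= fit_start_min) {
      if (upd.empty() || t[i] - t[upd.back()] + 1e-9 >= update_min)
        upd.push_back(i);
    }
  }
  int m = upd.size();
  NumericVector ut(m), tau(m), A(m), B(m), C(m), D(m), psp(m), fsp(m), conv(m);
  double prev_tau = -1.0;
  for (int j = 0; j < m; ++j) {
    int nj = upd[j] + 1;
    double coef[5], sse;
    double lo = tau_lo, hi = tau_hi;
    if (prev_tau > 0) { // warm bracket around the previous optimum
      lo = std::max(tau_lo, prev_tau / 3.0);
      hi = std::min(tau_hi, prev_tau * 3.0);
    }
    double tj = golden_tau(&t[0], &p[0], &f[0], nj, lo, hi, wf, coef, &sse);
    // expand to the full range if pinned at the warm bracket edge
    if (prev_tau > 0 && (tj <= lo * 1.02 || tj >= hi * 0.98)) {
      tj = golden_tau(&t[0], &p[0], &f[0], nj, tau_lo, tau_hi, wf, coef, &sse);
    }
    prev_tau = tj;
    ut[j] = t[upd[j]];
    tau[j] = tj; A[j] = coef[0]; B[j] = coef[1]; C[j] = coef[2]; D[j] = coef[3];
    conv[j] = coef[4];
    double u = std::exp(-ut[j] / tj);
    psp[j] = coef[0] * (1 - u) + coef[1];
    fsp[j] = coef[2] * u + coef[3];
  }
  return List::create(_["time_min"] = ut, _["tau"] = tau, _["A"] = A,
                      _["B"] = B, _["C"] = C, _["D"] = D,
                      _["ps_fit"] = psp, _["fs_fit"] = fsp,
                      _["converged"] = conv);
}
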