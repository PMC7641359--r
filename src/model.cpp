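// Core numerics for the reduced four-variable ventricular action potential
// model: Hodgkin-Huxley style gating rates transcribed from the 1991
// Luo-Rudy formulation, ionic currents, the mollified stimulus, an adaptive
// Dormand-Prince 5(4) integrator with dense output and section-crossing
// events, and the closed-form slow-manifold graph f = h(V, x) with the
// desingularized reduced flow used by the fast-slow analysis.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parameter vector layout (kept in sync with R/params.R):
//  0 Cm  1 gCa  2 gK  3 gK1  4 gKp  5 gb  6 VCa  7 VK  8 VK1  9 Vb
// 10 Ko 11 dV_d 12 dV_f 13 alpha 14 beta 15 f_pedestal
// 16 stim_amp 17 stim_dur 18 stim_onset 19 stim_smooth
struct Pars {
  double Cm, gCa, gK, gK1, gKp, gb, VCa, VK, VK1, Vb;
  double Ko, dVd, dVf, alpha, beta, fped;
  double stim_amp, stim_dur, stim_onset, stim_smooth;
};

static Pars unpack(const NumericVector& p) {
  Pars q;
  q.Cm = p[0]; q.gCa = p[1]; q.gK = p[2]; q.gK1 = p[3]; q.gKp = p[4];
  q.gb = p[5]; q.VCa = p[6]; q.VK = p[7]; q.VK1 = p[8]; q.Vb = p[9];
  q.Ko = p[10]; q.dVd = p[11]; q.dVf = p[12]; q.alpha = p[13]; q.beta = p[14];
  q.fped = p[15]; q.stim_amp = p[16]; q.stim_dur = p[17];
  q.stim_onset = p[18]; q.stim_smooth = p[19];
  return q;
}

// ---- LR-I rate functions (V in mV, rates in 1/ms) ----------------------
static inline double ad_rate(double V) {
  return 0.095 * std::exp(-0.01 * (V - 5.0)) / (1.0 + std::exp(-0.072 * (V - 5.0)));
}
static inline double bd_rate(double V) {
  return 0.07 * std::exp(-0.017 * (V + 44.0)) / (1.0 + std::exp(0.05 * (V + 44.0)));
}
static inline double af_rate(double V) {
  return 0.012 * std::exp(-0.008 * (V + 28.0)) / (1.0 + std::exp(0.15 * (V + 28.0)));
}
static inline double bf_rate(double V) {
  return 0.0065 * std::exp(-0.02 * (V + 30.0)) / (1.0 + std::exp(-0.2 * (V + 30.0)));
}
static inline double ax_rate(double V) {
  return 0.0005 * std::exp(0.083 * (V + 50.0)) / (1.0 + std::exp(0.057 * (V + 50.0)));
}
static inline double bx_rate(double V) {
  return 0.0013 * std::exp(-0.06 * (V + 20.0)) / (1.0 + std::exp(-0.04 * (V + 20.0)));
}

// Instantaneous IK rectification factor; removable singularity at V = -77.
static inline double xi_inf(double V) {
  if (V <= -100.0) return 1.0;
  double u = V + 77.0;
  double expm = (std::fabs(u) < 1e-7) ? 0.04 * (1.0 + 0.02 * u)
                                      : (std::exp(0.04 * u) - 1.0) / u;
  return 2.837 * expm / std::exp(0.04 * (V + 35.0));
}

static inline double k1_inf(double V, double VK1) {
  double dv = V - VK1;
  double a = 1.02 / (1.0 + std::exp(0.2385 * (dv - 59.215)));
  double b = (0.49124 * std::exp(0.08032 * (dv + 5.476)) +
              std::exp(0.06175 * (dv - 594.31))) /
             (1.0 + std::exp(-0.5143 * (dv + 4.753)));
  return a / (a + b);
}

static inline double kp_inf(double V) {
  return 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
}

struct Gates {
  double dinf, finf, xinf, taud, tauf, taux, xi, k1, kp;
};

// Window shifts translate the steady-state curves only; time constants keep
// their default voltage dependence, scaled globally by alpha (tau_d) and
// beta (tau_f).
static Gates gates_at(double V, const Pars& p) {
  Gates g;
  double Vd = V - p.dVd, Vf = V - p.dVf;
  double ad = ad_rate(Vd), bd = bd_rate(Vd);
  double af = af_rate(Vf), bf = bf_rate(Vf);
  double ax = ax_rate(V), bx = bx_rate(V);
  g.dinf = ad / (ad + bd);
  g.finf = p.fped + (1.0 - p.fped) * (af / (af + bf));
  g.xinf = ax / (ax + bx);
  double ad0 = ad_rate(V), bd0 = bd_rate(V);
  double af0 = af_rate(V), bf0 = bf_rate(V);
  g.taud = p.alpha / (ad0 + bd0);
  g.tauf = p.beta / (af0 + bf0);
  g.taux = 1.0 / (ax + bx);
  g.xi = xi_inf(V);
  g.k1 = k1_inf(V, p.VK1);
  g.kp = kp_inf(V);
  return g;
}

// Total ionic current (outward positive), d, f, x free.
static inline double total_current(double V, double d, double f, double x,
                                   const Pars& p, const Gates& g) {
  double ica = p.gCa * d * f * (V - p.VCa);
  double ik  = p.gK * x * g.xi * (V - p.VK);
  double ik1 = p.gK1 * g.k1 * (V - p.VK1);
  double ikp = p.gKp * g.kp * (V - p.VK1);
  double ib  = p.gb * (V - p.Vb);
  return ica + ik + ik1 + ikp + ib;
}

static inline double stim_at(double t, const Pars& p) {
  if (p.stim_amp == 0.0) return 0.0;
  double w = p.stim_smooth;
  double up = 1.0 / (1.0 + std::exp(-(t - p.stim_onset) / w));
  double dn = 1.0 / (1.0 + std::exp(-(p.stim_onset + p.stim_dur - t) / w));
  return p.stim_amp * up * dn;
}

static void rhs_full(double t, const double* y, double* dy, const Pars& p,
                     bool use_stim) {
  double V = y[0], d = y[1], f = y[2], x = y[3];
  Gates g = gates_at(V, p);
  double Iion = total_current(V, d, f, x, p, g);
  double Is = use_stim ? stim_at(t, p) : 0.0;
  dy[0] = (-Iion + Is) / p.Cm;
  dy[1] = (g.dinf - d) / g.taud;
  dy[2] = (g.finf - f) / g.tauf;
  dy[3] = (g.xinf - x) / g.taux;
}

// ---- slow-manifold graph f = h(V, x) ------------------------------------
// F(V, f, x) = total current with d = d_inf(V); affine in f, so solvable in
// closed form wherever the ICa-L coefficient is nonzero.
static inline double h_graph(double V, double x, const Pars& p) {
  Gates g = gates_at(V, p);
  double denom = p.gCa * g.dinf * (V - p.VCa);
  double G = p.gK * x * g.xi * (V - p.VK) + p.gK1 * g.k1 * (V - p.VK1) +
             p.gKp * g.kp * (V - p.VK1) + p.gb * (V - p.Vb);
  return -G / denom;
}

static inline double hV_graph(double V, double x, const Pars& p) {
  const double dh = 1e-4;  // mV; h is smooth, central difference suffices
  return (h_graph(V + dh, x, p) - h_graph(V - dh, x, p)) / (2.0 * dh);
}

static inline double hx_graph(double V, double x, const Pars& p) {
  Gates g = gates_at(V, p);
  double denom = p.gCa * g.dinf * (V - p.VCa);
  return -(p.gK * g.xi * (V - p.VK)) / denom;
}

// Desingularized reduced flow in graph coordinates (V, x).
static void rhs_desing(const double* y, double* dy, const Pars& p, int dir) {
  double V = y[0], x = y[1];
  Gates g = gates_at(V, p);
  double h = h_graph(V, x, p);
  double gf = (g.finf - h) / g.tauf;
  double gx = (g.xinf - x) / g.taux;
  dy[0] = dir * (gf - hx_graph(V, x, p) * gx);
  dy[1] = dir * (hV_graph(V, x, p) * gx);
}

// ---- Dormand-Prince 5(4) ------------------------------------------------
struct StepperResult {
  std::vector<double> t_out;
  std::vector<std::vector<double> > y_out;
  std::vector<double> ev_t;
  std::vector<std::vector<double> > ev_y;
  int status;        // 0 ok, 1 step-size collapse, 2 stopped on event
  double fail_time;
};

// Generic RHS interface
typedef void (*RhsFun)(double, const double*, double*, const Pars&, int);

static void rhs_full_wrap(double t, const double* y, double* dy, const Pars& p,
                          int flag) {
  // flag: +1 with stimulus, 0 autonomous, -1 autonomous time-reversed
  if (flag > 0) rhs_full(t, y, dy, p, true);
  else {
    rhs_full(t, y, dy, p, false);
    if (flag < 0) for (int i = 0; i < 4; ++i) dy[i] = -dy[i];
  }
}

static void rhs_desing_wrap(double t, const double* y, double* dy,
                            const Pars& p, int flag) {
  (void)t;
  rhs_desing(y, dy, p, flag >= 0 ? 1 : -1);
}

// Cubic Hermite interpolation on [t0, t0+h]
static inline void hermite(double th, double h, const double* y0,
                           const double* f0, const double* y1,
                           const double* f1, int n, double* out) {
  double s = th / h;
  double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
  double h10 = s * (1 - s) * (1 - s);
  double h01 = s * s * (3 - 2 * s);
  double h11 = s * s * (s - 1);
  for (int i = 0; i < n; ++i)
    out[i] = h00 * y0[i] + h * h10 * f0[i] + h01 * y1[i] + h * h11 * f1[i];
}

static StepperResult dp5(RhsFun rhs, int n, const Pars& p, int flag,
                         const std::vector<double>& y0v, double t0,
                         double t_end, double out_dt, double rtol, double atol,
                         double hmax, int ev_idx, double ev_val, int ev_dir,
                         int max_events, int stop_after) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
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
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  StepperResult res;
  res.status = 0;
  res.fail_time = NA_REAL;

  std::vector<double> y(y0v), ynew(n), yerr(n), ytmp(n), yint(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  double t = t0;
  double next_out = t0;
  const double hmin = 1e-12;
  double h = 1e-3;
  if (hmax <= 0) hmax = 5.0;  // ms; plateau dynamics are slower than this
  rhs(t, y.data(), k1.data(), p, flag);

  int nev = 0;
  bool stopped = false;
  long max_steps = 100000000L;
  for (long step = 0; step < max_steps && t < t_end && !stopped; ++step) {
    if (h > hmax) h = hmax;
    if (t + h > t_end) h = t_end - t;

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(t + c2 * h, ytmp.data(), k2.data(), p, flag);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(t + c3 * h, ytmp.data(), k3.data(), p, flag);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(t + c4 * h, ytmp.data(), k4.data(), p, flag);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(t + c5 * h, ytmp.data(), k5.data(), p, flag);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(t + h, ytmp.data(), k6.data(), p, flag);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(t + h, ynew.data(), k7.data(), p, flag);

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) err = 1e10;  // overflow in a trial stage

    if (err <= 1.0) {
      // accepted: dense output on uniform grid
      if (out_dt > 0) {
        while (next_out <= t + h + 1e-12 && next_out <= t_end + 1e-12) {
          hermite(next_out - t, h, y.data(), k1.data(), ynew.data(),
                  k7.data(), n, yint.data());
          res.t_out.push_back(next_out);
          res.y_out.push_back(yint);
          next_out += out_dt;
        }
      } else {
        res.t_out.push_back(t + h);
        res.y_out.push_back(ynew);
      }
      // event detection on component ev_idx crossing ev_val
      if (ev_idx >= 0 && nev < max_events) {
        const int nsub = 6;
        double ta = 0.0, va = y[ev_idx] - ev_val;
        std::vector<double> ya(y);
        for (int ss = 1; ss <= nsub && nev < max_events && !stopped; ++ss) {
          double tb = h * ss / nsub;
          double vb;
          if (ss == nsub) { vb = ynew[ev_idx] - ev_val; }
          else {
            hermite(tb, h, y.data(), k1.data(), ynew.data(), k7.data(), n,
                    yint.data());
            vb = yint[ev_idx] - ev_val;
          }
          bool crossed = (va <= 0 && vb > 0 && ev_dir >= 0) ||
                         (va >= 0 && vb < 0 && ev_dir <= 0);
          if (ev_dir == 0) crossed = (va <= 0 && vb > 0) || (va >= 0 && vb < 0);
          if (crossed && va != vb) {
            double lo = ta, hi = tb;
            for (int it = 0; it < 60; ++it) {
              double mid = 0.5 * (lo + hi);
              hermite(mid, h, y.data(), k1.data(), ynew.data(), k7.data(), n,
                      yint.data());
              double vm = yint[ev_idx] - ev_val;
              if ((va <= 0) == (vm <= 0)) lo = mid; else hi = mid;
            }
            double tc = 0.5 * (lo + hi);
            hermite(tc, h, y.data(), k1.data(), ynew.data(), k7.data(), n,
                    yint.data());
            res.ev_t.push_back(t + tc);
            res.ev_y.push_back(yint);
            ++nev;
            if (stop_after > 0 && nev >= stop_after) {
              res.status = 2;
              stopped = true;
            }
          }
          ta = tb; va = vb;
        }
      }
      t += h;
      y = ynew;
      k1 = k7;  // FSAL
      double fac = 0.9 * std::pow(err > 1e-14 ? err : 1e-14, -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      if (!std::isfinite(fac) || fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < hmin) {
        res.status = 1;
        res.fail_time = t;
        break;
      }
    }
    bool diverged = !std::isfinite(y[0]) || std::fabs(y[0]) > 500.0;
    if (n == 4)  // gates physically in [0,1]; well beyond that is blow-up
      for (int i = 1; i < 4; ++i)
        if (!std::isfinite(y[i]) || std::fabs(y[i]) > 5.0) diverged = true;
    if (diverged) {
      res.status = 1;
      res.fail_time = t;
      break;
    }
  }
  return res;
}

static List pack_result(const StepperResult& r, int n) {
  int nt = r.t_out.size();
  NumericVector tt(nt);
  NumericMatrix yy(nt, n);
  for (int i = 0; i < nt; ++i) {
    tt[i] = r.t_out[i];
    for (int j = 0; j < n; ++j) yy(i, j) = r.y_out[i][j];
  }
  int ne = r.ev_t.size();
  NumericVector et(ne);
  NumericMatrix ey(ne, n);
  for (int i = 0; i < ne; ++i) {
    et[i] = r.ev_t[i];
    for (int j = 0; j < n; ++j) ey(i, j) = r.ev_y[i][j];
  }
  return List::create(_["t"] = tt, _["y"] = yy, _["ev_t"] = et,
                      _["ev_y"] = ey, _["status"] = r.status,
                      _["fail_time"] = r.fail_time);
}

// ---- exported interface -------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gating(NumericVector V, NumericVector params) {
  Pars p = unpack(params);
  int n = V.size();
  NumericMatrix out(n, 9);
  colnames(out) = CharacterVector::create("d_inf", "f_inf", "x_inf", "tau_d",
                                          "tau_f", "tau_x", "Xi_inf",
                                          "K1_inf", "Kp_inf");
  for (int i = 0; i < n; ++i) {
    Gates g = gates_at(V[i], p);
    out(i, 0) = g.dinf; out(i, 1) = g.finf; out(i, 2) = g.xinf;
    out(i, 3) = g.taud; out(i, 4) = g.tauf; out(i, 5) = g.taux;
    out(i, 6) = g.xi;   out(i, 7) = g.k1;   out(i, 8) = g.kp;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_currents(NumericVector state, NumericVector params) {
  Pars p = unpack(params);
  double V = state[0], d = state[1], f = state[2], x = state[3];
  Gates g = gates_at(V, p);
  NumericVector out(5);
  out[0] = p.gCa * d * f * (V - p.VCa);
  out[1] = p.gK * x * g.xi * (V - p.VK);
  out[2] = p.gK1 * g.k1 * (V - p.VK1);
  out[3] = p.gKp * g.kp * (V - p.VK1);
  out[4] = p.gb * (V - p.Vb);
  out.names() = CharacterVector::create("ICaL", "IK", "IK1", "IKp", "Ib");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stimulus(NumericVector t, NumericVector params) {
  Pars p = unpack(params);
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = stim_at(t[i], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(double t, NumericVector state, NumericVector params,
                      bool use_stim = true) {
  Pars p = unpack(params);
  NumericVector dy(4);
  double y[4] = {state[0], state[1], state[2], state[3]};
  double d[4];
  rhs_full(t, y, d, p, use_stim);
  for (int i = 0; i < 4; ++i) dy[i] = d[i];
  return dy;
}

// Steady-state current balance S(V): total current with all gates at their
// steady-state curves; roots are full-system equilibria.
// [[Rcpp::export]]
NumericVector cpp_ss_current(NumericVector V, NumericVector params) {
  Pars p = unpack(params);
  int n = V.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Gates g = gates_at(V[i], p);
    out[i] = total_current(V[i], g.dinf, g.finf, g.xinf, p, g);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector params, NumericVector y0, double t0,
                   double t_end, double out_dt, double rtol, double atol,
                   double hmax, int flag, double sec_V, int sec_dir,
                   int max_events, int stop_after) {
  Pars p = unpack(params);
  std::vector<double> y(4);
  for (int i = 0; i < 4; ++i) y[i] = y0[i];
  int ev_idx = (max_events > 0) ? 0 : -1;
  StepperResult r = dp5(rhs_full_wrap, 4, p, flag, y, t0, t_end, out_dt,
                        rtol, atol, hmax, ev_idx, sec_V, sec_dir,
                        max_events, stop_after);
  return pack_result(r, 4);
}

// [[Rcpp::export]]
double cpp_h(double V, double x, NumericVector params) {
  return h_graph(V, x, unpack(params));
}

// [[Rcpp::export]]
double cpp_hV(double V, double x, NumericVector params) {
  return hV_graph(V, x, unpack(params));
}

// [[Rcpp::export]]
double cpp_hx(double V, double x, NumericVector params) {
  return hx_graph(V, x, unpack(params));
}

// [[Rcpp::export]]
NumericVector cpp_desing_rhs(double V, double x, NumericVector params) {
  Pars p = unpack(params);
  double y[2] = {V, x}, d[2];
  rhs_desing(y, d, p, 1);
  return NumericVector::create(d[0], d[1]);
}

// [[Rcpp::export]]
List cpp_integrate_desing(NumericVector params, NumericVector y0,
                          double t_end, double out_dt, double rtol,
                          double atol, int dir, double hmax = -1.0) {
  Pars p = unpack(params);
  std::vector<double> y(2);
  y[0] = y0[0]; y[1] = y0[1];
  if (hmax <= 0) hmax = t_end / 100.0;
  StepperResult r = dp5(rhs_desing_wrap, 2, p, dir, y, 0.0, t_end, out_dt,
                        rtol, atol, hmax, -1, 0.0, 0, 0, 0);
  return pack_result(r, 2);
}
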