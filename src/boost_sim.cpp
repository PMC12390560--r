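#include <Rcpp.h>
using namespace Rcpp;

// Averaged continuous-conduction boost model with a discrete PI voltage loop.
//
// State: inductor current I (A, floored at 0 as a discontinuous-conduction
// guard) and capacitor voltage V (V). Plant:
//   dI/dt = (v_in - r_l * I - (1 - d) * V) / L
//   dV/dt = ((1 - d) * I - v_meas / R) / C
// The measured output includes the capacitor ESR drop,
//   v_meas = V + esr * i_C,  i_C = (1 - d) * I - v_meas / R
// solved exactly for the resistive load:
//   v_meas = (V + esr * (1 - d) * I) / (1 + esr / R).
//
// The controller runs at f_ctrl with per-update discrete PI gains (duty per
// volt, duty per volt-update) and conditional-integration anti-windup; the
// plant is integrated with classical RK4 at dt between control updates.

struct Plant {
  double v_in, L, C, esr, r_l;
};

static inline double v_measured(const Plant &p, double I, double V,
                                double d, double R) {
  return (V + p.esr * (1.0 - d) * I) / (1.0 + p.esr / R);
}

static inline void deriv(const Plant &p, double I, double V, double d,
                         double R, double &dI, double &dV) {
  double vm = v_measured(p, I, V, d, R);
  dI = (p.v_in - p.r_l * I - (1.0 - d) * V) / p.L;
  dV = ((1.0 - d) * I - vm / R) / p.C;
}

// [[Rcpp::export]]
List boost_sim_core(double v_in, double L, double C, double esr, double r_l,
                    double duty_max, double kp, double ki, double setpoint,
                    double integrator_limit, double f_ctrl, double dt,
                    NumericVector load_breaks, NumericVector load_res,
                    double duration, double v0, double i0,
                    double duty_fixed) {
  Plant p{v_in, L, C, esr, r_l};
  const int n_ctrl = (int)std::lround(duration * f_ctrl);
  const int sub = (int)std::lround(1.0 / (f_ctrl * dt));
  const double h = 1.0 / (f_ctrl * (double)sub);

  NumericVector t_out(n_ctrl), v_out(n_ctrl), i_out(n_ctrl), d_out(n_ctrl),
      r_out(n_ctrl);

  double I = i0, V = v0, S = 0.0, d = 0.0;
  const double s_lim = (ki > 0.0) ? integrator_limit / ki : R_PosInf;
  int li = 0;
  const int nl = load_breaks.size();

  for (int k = 0; k < n_ctrl; ++k) {
    double t = (double)k / f_ctrl;
    while (li + 1 < nl && t >= load_breaks[li + 1]) ++li;
    double R = load_res[li];

    double vm = v_measured(p, I, V, d, R);
    double e = setpoint - vm;

    if (duty_fixed >= 0.0) {  // open-loop characterisation mode
      d = duty_fixed;
      t_out[k] = t; v_out[k] = vm; i_out[k] = I; d_out[k] = d; r_out[k] = R;
      for (int m = 0; m < sub; ++m) {
        double k1I, k1V, k2I, k2V, k3I, k3V, k4I, k4V;
        deriv(p, I, V, d, R, k1I, k1V);
        deriv(p, I + 0.5 * h * k1I, V + 0.5 * h * k1V, d, R, k2I, k2V);
        deriv(p, I + 0.5 * h * k2I, V + 0.5 * h * k2V, d, R, k3I, k3V);
        deriv(p, I + h * k3I, V + h * k3V, d, R, k4I, k4V);
        I += h / 6.0 * (k1I + 2.0 * k2I + 2.0 * k3I + k4I);
        V += h / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
        if (I < 0.0) I = 0.0;
        if (std::fabs(V) > 10.0 * setpoint) {
          stop("boost simulation unstable: |v_out| exceeded 10 x setpoint at t = %f s",
               t);
        }
      }
      continue;
    }

    double S2 = S + e;
    if (S2 > s_lim) S2 = s_lim;
    if (S2 < -s_lim) S2 = -s_lim;
    double u = kp * e + ki * S2;
    d = u;
    if (d > duty_max) d = duty_max;
    if (d < 0.0) d = 0.0;
    // conditional integration: while the clamped actuator is saturated
    // against the error sign, the integrator does not advance
    if ((d >= duty_max && e > 0.0) || (d <= 0.0 && e < 0.0)) S2 = S;
    S = S2;

    t_out[k] = t; v_out[k] = vm; i_out[k] = I; d_out[k] = d; r_out[k] = R;

    for (int m = 0; m < sub; ++m) {
      double k1I, k1V, k2I, k2V, k3I, k3V, k4I, k4V;
      deriv(p, I, V, d, R, k1I, k1V);
      deriv(p, I + 0.5 * h * k1I, V + 0.5 * h * k1V, d, R, k2I, k2V);
      deriv(p, I + 0.5 * h * k2I, V + 0.5 * h * k2V, d, R, k3I, k3V);
      deriv(p, I + h * k3I, V + h * k3V, d, R, k4I, k4V);
      I += h / 6.0 * (k1I + 2.0 * k2I + 2.0 * k3I + k4I);
      V += h / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
      if (I < 0.0) I = 0.0;  // diode: no reverse inductor current
      if (std::fabs(V) > 10.0 * setpoint) {
        stop("boost simulation unstable: |v_out| exceeded 10 x setpoint at t = %f s",
             t);
      }
    }
  }
  return List::create(_["time_s"] = t_out, _["v_out"] = v_out,
                      _["i_l"] = i_out, _["duty"] = d_out,
                      _["load_ohm"] = r_out, _["v_final"] = V,
                      _["i_final"] = I);
}
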