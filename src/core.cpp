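// Compiled core: Euler integration of the spiking loop, the dopamine
// neuron, and alpha-kernel trace superposition. The membrane updates are
// the same formulas as the R reference steppers (step_msn / step_qif);
// tests assert step-by-step equivalence.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Izh {
  double C, vr, vt, k, a, b, c, d, vpeak;
  explicit Izh(const NumericVector& p)
    : C(p["C"]), vr(p["vr"]), vt(p["vt"]), k(p["k"]), a(p["a"]),
      b(p["b"]), c(p["c"]), d(p["d"]), vpeak(p["vpeak"]) {}
  // One Euler step; returns true on spike.
  bool step(double& v, double& u, double I, double dt) const {
    double v_new = v + dt * (k * (v - vr) * (v - vt) - u + I) / C;
    double u_new = u + dt * a * (b * (v - vr) - u);
    bool spiked = v_new >= vpeak;
    if (spiked) { v_new = c; u_new += d; }
    v = v_new; u = u_new;
    return spiked;
  }
};

struct Qif {
  double C, vr, vt, k, vreset, vpeak;
  explicit Qif(const NumericVector& p)
    : C(p["C"]), vr(p["vr"]), vt(p["vt"]), k(p["k"]),
      vreset(p["vreset"]), vpeak(p["vpeak"]) {}
  bool step(double& v, double I, double dt) const {
    double v_new = v + dt * (k * (v - vr) * (v - vt) + I) / C;
    bool spiked = v_new >= vpeak;
    if (spiked) v_new = vreset;
    v = v_new;
    return spiked;
  }
};

void check_finite(double v, const char* unit, double t_ms) {
  if (!std::isfinite(v))
    stop("non-finite membrane potential in %s unit at t = %.1f ms",
         unit, t_ms);
}

}  // namespace

// Trace of a spike train: sum of unit-peak alpha kernels
// s * exp(1 - s), s = (t - spike - lag) / lambda, sampled on t_grid.
// [[Rcpp::export]]
NumericVector cpp_spike_trace(NumericVector spikes, double lag,
                              double lambda, NumericVector t_grid) {
  int n = t_grid.size();
  NumericVector out(n);
  double support = lag + 30.0 * lambda;  // kernel negligible beyond this
  for (int si = 0; si < spikes.size(); ++si) {
    double t0 = spikes[si];
    // first grid index with t >= t0 + lag (grid is sorted)
    int lo = std::lower_bound(t_grid.begin(), t_grid.end(), t0 + lag) -
             t_grid.begin();
    for (int i = lo; i < n; ++i) {
      double dtc = t_grid[i] - t0;
      if (dtc > support) break;
      double s = (dtc - lag) / lambda;
      if (s > 0) out[i] += s * std::exp(1.0 - s);
    }
  }
  return out;
}

// Constant-current integration of a two-variable (Izhikevich-form) unit.
// [[Rcpp::export]]
NumericVector cpp_izh_constant(NumericVector params, double I,
                               double duration, double dt) {
  Izh u(params);
  double v = u.vr, w = 0.0;
  std::vector<double> spikes;
  int n = (int)std::round(duration / dt);
  for (int t = 1; t <= n; ++t) {
    if (u.step(v, w, I, dt)) spikes.push_back(t * dt);
    check_finite(v, "izhikevich", t * dt);
  }
  return wrap(spikes);
}

// Constant-current integration of a QIF unit.
// [[Rcpp::export]]
NumericVector cpp_qif_constant(NumericVector params, double I,
                               double duration, double dt) {
  Qif u(params);
  double v = u.vr;
  std::vector<double> spikes;
  int n = (int)std::round(duration / dt);
  for (int t = 1; t <= n; ++t) {
    if (u.step(v, I, dt)) spikes.push_back(t * dt);
    check_finite(v, "qif", t * dt);
  }
  return wrap(spikes);
}

// Dopamine neuron over [t_start, t_end]: tonic drive plus a current step
// of height burst_I during [burst_onset, burst_onset + burst_dur).
// Times are in the trace frame (response = 0).
// [[Rcpp::export]]
NumericVector cpp_simulate_da(NumericVector params, double t_start,
                              double t_end, double dt, double tonic_I,
                              double burst_I, double burst_onset,
                              double burst_dur) {
  Izh u(params);
  double v = u.vr, w = 0.0;
  std::vector<double> spikes;
  int n = (int)std::round((t_end - t_start) / dt);
  for (int i = 1; i <= n; ++i) {
    double t = t_start + i * dt;
    double I = tonic_I;
    if (t >= burst_onset && t < burst_onset + burst_dur) I += burst_I;
    if (u.step(v, w, I, dt)) spikes.push_back(t);
    check_finite(v, "dopamine", t);
  }
  return wrap(spikes);
}

// Full two-channel loop for one trial. drive: per-MSN cortical current.
// Channels: 0 = A, 1 = B. Simulation stops at the first premotor output
// threshold crossing (response-terminated stimulus).
// [[Rcpp::export]]
List cpp_simulate_trial(NumericVector msn_params, NumericVector qif_params,
                        NumericVector drive, List net,
                        bool return_dynamics) {
  Izh msn(msn_params);
  Qif qif(qif_params);
  const double dt = net["dt"], duration = net["duration"];
  const double sigma_C = net["sigma_C"], threshold = net["threshold"];
  const double tau_syn = net["tau_syn"], tau_pm = net["tau_pm"];
  const double g_msn_msn = net["g_msn_msn"], g_msn_gpi = net["g_msn_gpi"];
  const double I_gpi = net["I_gpi"], g_gpi_thal = net["g_gpi_thal"];
  const double I_thal = net["I_thal"], g_thal_pm = net["g_thal_pm"];
  const double g_pm_pm = net["g_pm_pm"];
  const double syn_decay = std::exp(-dt / tau_syn);
  const double kE = std::exp(1.0);

  double v_msn[2] = {msn.vr, msn.vr}, u_msn[2] = {0, 0};
  double v_gpi[2] = {qif.vr, qif.vr};
  double v_thal[2] = {qif.vr, qif.vr};
  double v_pm[2] = {qif.vr, qif.vr};
  double s_msn[2] = {0, 0}, s_gpi[2] = {0, 0}, s_thal[2] = {0, 0},
         s_pm[2] = {0, 0};
  double a_pm[2] = {0, 0}, o_pm[2] = {0, 0};

  // Warm-up without cortical drive: settles the tonic GPi / suppressed
  // thalamus balance before stimulus onset. Premotor filters are reset
  // afterwards so output integration starts at stimulus onset.
  int warm_steps = (int)std::round(200.0 / dt);
  for (int t = 1; t <= warm_steps; ++t) {
    double s_msn_now[2] = {s_msn[0], s_msn[1]};
    double s_gpi_now[2] = {s_gpi[0], s_gpi[1]};
    for (int j = 0; j < 2; ++j) {
      s_msn[j] *= syn_decay; s_gpi[j] *= syn_decay;
      s_thal[j] *= syn_decay; s_pm[j] *= syn_decay;
    }
    for (int j = 0; j < 2; ++j) {
      if (msn.step(v_msn[j], u_msn[j], -g_msn_msn * s_msn_now[1 - j], dt))
        s_msn[j] += 1;
      if (qif.step(v_gpi[j], I_gpi - g_msn_gpi * s_msn_now[j], dt))
        s_gpi[j] += 1;
      if (qif.step(v_thal[j], I_thal - g_gpi_thal * s_gpi_now[j], dt))
        s_thal[j] += 1;
    }
  }
  for (int j = 0; j < 2; ++j) {
    s_thal[j] = 0; s_pm[j] = 0; a_pm[j] = 0; o_pm[j] = 0;
    v_pm[j] = qif.vr;
  }

  int n_steps = (int)std::round(duration / dt);
  std::vector<double> sp_msn[2], sp_gpi[2], sp_thal[2], sp_pm[2];
  NumericMatrix out_dyn;
  if (return_dynamics) out_dyn = NumericMatrix(n_steps, 2);

  int response = -1;
  double rt = duration;
  bool crossed = false;

  for (int t = 1; t <= n_steps; ++t) {
    double t_ms = t * dt;
    double s_msn_now[2] = {s_msn[0], s_msn[1]};
    double s_gpi_now[2] = {s_gpi[0], s_gpi[1]};
    double s_thal_now[2] = {s_thal[0], s_thal[1]};
    double s_pm_now[2] = {s_pm[0], s_pm[1]};
    for (int j = 0; j < 2; ++j) {
      s_msn[j] *= syn_decay; s_gpi[j] *= syn_decay;
      s_thal[j] *= syn_decay; s_pm[j] *= syn_decay;
    }
    for (int j = 0; j < 2; ++j) {
      double I_m = drive[j] - g_msn_msn * s_msn_now[1 - j];
      if (msn.step(v_msn[j], u_msn[j], I_m, dt)) {
        s_msn[j] += 1; sp_msn[j].push_back(t_ms);
      }
      check_finite(v_msn[j], "msn", t_ms);
      if (qif.step(v_gpi[j], I_gpi - g_msn_gpi * s_msn_now[j], dt)) {
        s_gpi[j] += 1; if (return_dynamics) sp_gpi[j].push_back(t_ms);
      }
      if (qif.step(v_thal[j], I_thal - g_gpi_thal * s_gpi_now[j], dt)) {
        s_thal[j] += 1; if (return_dynamics) sp_thal[j].push_back(t_ms);
      }
      double I_p = g_thal_pm * s_thal_now[j] - g_pm_pm * s_pm_now[1 - j];
      if (sigma_C > 0) I_p += sigma_C * norm_rand();
      if (qif.step(v_pm[j], I_p, dt)) {
        s_pm[j] += 1; a_pm[j] += kE;
        if (return_dynamics) sp_pm[j].push_back(t_ms);
      }
      check_finite(v_pm[j], "premotor", t_ms);
      // alpha cascade: o is the smoothed cumulative spike activation
      double a_old = a_pm[j];
      a_pm[j] += -dt * a_pm[j] / tau_pm;
      o_pm[j] += dt * (a_old - o_pm[j]) / tau_pm;
      if (return_dynamics) out_dyn(t - 1, j) = o_pm[j];
    }
    bool cA = o_pm[0] >= threshold, cB = o_pm[1] >= threshold;
    if (cA || cB) {
      crossed = true;
      rt = t_ms;
      if (cA && cB) response = (unif_rand() < 0.5) ? 0 : 1;
      else response = cA ? 0 : 1;
      if (return_dynamics && t < n_steps)
        out_dyn = out_dyn(Range(0, t - 1), Range(0, 1));
      break;
    }
  }
  if (response < 0) response = (unif_rand() < 0.5) ? 0 : 1;

  List res = List::create(
    _["response"] = response,
    _["response_time"] = rt,
    _["crossed"] = crossed,
    _["msn_spikes"] = List::create(wrap(sp_msn[0]), wrap(sp_msn[1])));
  if (return_dynamics) {
    res["premotor_output"] = out_dyn;
    res["gpi_spikes"] = List::create(wrap(sp_gpi[0]), wrap(sp_gpi[1]));
    res["thal_spikes"] = List::create(wrap(sp_thal[0]), wrap(sp_thal[1]));
    res["pm_spikes"] = List::create(wrap(sp_pm[0]), wrap(sp_pm[1]));
  }
  return res;
}
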