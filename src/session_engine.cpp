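#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inner Euler loop of the two-compartment session. All model logic here
// mirrors the pure-R reference engine in R/session.R; the R functions
// g_dend(), g_prop(), weight_update() etc. are the documented
// single-step primitives and the tests check the two engines against
// each other.

static inline bool in_region(double pf, double r0, double r1) {
  if (r0 <= r1) return pf >= r0 && pf < r1;
  return pf >= r0 || pf < r1;
}

// [[Rcpp::export(name = ".session_engine_cpp")]]
List session_engine_cpp(List par,
                        NumericVector centers,
                        NumericVector gains,
                        NumericVector offsets,
                        NumericVector w0,
                        double r_dend0, double r_soma0,
                        int n_laps, int n_bins,
                        bool plasticity,
                        bool novelty_enabled,
                        NumericVector reset_times,
                        double input_novelty_coef,
                        double I_dend_const, double I_soma_const,
                        bool const_inhib,
                        NumericMatrix inductions,
                        double t0,
                        double gain_noise_sd, double rate_noise_sd) {
  const double tau0 = par["tau0"], dt = par["dt"];
  const double a1 = par["alpha1"], a2 = par["alpha2"], I0 = par["I0"];
  const double Nth = par["N_th"], th_prop = par["theta_prop"];
  const double eta_ex = par["eta_ex"], eta_homeo = par["eta_homeo"];
  const double th_homeo = par["theta_homeo"];
  const double A = par["A_pre"], sig = par["sigma_pre"];
  const double tau_n = par["tau_n"];
  const double Id0 = par["I_dend_0"], Idinf = par["I_dend_inf"];
  const double Is0 = par["I_soma_0"], Isinf = par["I_soma_inf"];
  const double Eint = par["E_soma_int"];
  const double L = par["L"], v = par["v"];
  const bool gate_enabled = as<bool>(par["gate_enabled"]);
  const bool gate_strict = as<bool>(par["gate_strict"]);
  const bool linear = as<std::string>(par["dendrite_mode"]) == "linear";
  const bool clip_w = as<bool>(par["clip_weights"]);
  const double w_max = par["w_max"];
  const double I0lin = I0 * (a1 + a2) / a1;

  const int n_pre = w0.size();
  const int steps = (int)(L / (v * dt) + 0.5);
  const double binw = L / n_bins;
  const int lap_offset = (int)(v * t0 / L + 0.5);

  std::vector<double> w(w0.begin(), w0.end());
  double r_d = r_dend0, r_s = r_soma0;

  NumericMatrix map_d(n_laps, n_bins), map_s(n_laps, n_bins),
      map_u(n_laps, n_bins), map_p(n_laps, n_bins);
  IntegerMatrix map_cnt(n_laps, n_bins);
  NumericVector mean_d(n_laps), mean_s(n_laps), nov_lap(n_laps),
      Id_lap(n_laps), Is_lap(n_laps);
  NumericMatrix w_snap(n_laps + 1, n_pre);
  NumericMatrix r_snap(n_laps + 1, 2);
  IntegerVector spikes(n_laps);
  int first_spike_lap = 0;
  double prev_pdend = -1e300;

  std::vector<double> R(n_pre);
  std::vector<double> lap_gain(gains.begin(), gains.end());
  std::vector<double> lap_off(offsets.begin(), offsets.end());
  const bool lap_noise = gain_noise_sd > 0 || rate_noise_sd > 0;
  const int n_ind = inductions.nrow();

  for (int lap = 0; lap < n_laps; ++lap) {
    for (int j = 0; j < n_pre; ++j) w_snap(lap, j) = w[j];
    r_snap(lap, 0) = r_d;
    r_snap(lap, 1) = r_s;
    const int abs_lap = lap_offset + lap + 1;  // 1-based session lap
    if (lap_noise) {
      // per-lap input noise: multiplicative place-field gain and
      // rectified additive rate offsets, one draw per neuron per lap
      GetRNGstate();
      if (gain_noise_sd > 0)
        for (int j = 0; j < n_pre; ++j)
          lap_gain[j] = gains[j] * R::rnorm(1.0, gain_noise_sd);
      if (rate_noise_sd > 0)
        for (int j = 0; j < n_pre; ++j) {
          double off = R::rnorm(0.0, rate_noise_sd);
          lap_off[j] = offsets[j] + (off > 0 ? off : 0.0);
        }
      PutRNGstate();
    }
    double acc_d = 0, acc_s = 0;

    for (int s = 0; s < steps; ++s) {
      const double t = t0 + ((double)lap * steps + s) * dt;
      double x = v * t;
      double p = x - L * std::floor(x / L);
      if (p >= L) p -= L;

      // novelty and scheduled inhibition
      double tref = 0.0;
      for (int k = 0; k < reset_times.size(); ++k)
        if (reset_times[k] <= t && reset_times[k] > tref)
          tref = reset_times[k];
      const double n = novelty_enabled ? std::exp(-(t - tref) / tau_n) : 1.0;
      double I_dend = Idinf - (Idinf - Id0) * n;
      double I_soma = Isinf - (Isinf - Is0) * n;
      if (const_inhib) { I_dend = I_dend_const; I_soma = I_soma_const; }

      // protocol currents
      double Id_ext = 0, Is_ext = 0, suppress = 0;
      for (int k = 0; k < n_ind; ++k) {
        if (abs_lap < inductions(k, 3) || abs_lap > inductions(k, 4)) continue;
        if (!in_region(p / L, inductions(k, 1), inductions(k, 2))) continue;
        const int kind = (int)inductions(k, 0);
        if (kind == 1) Id_ext += inductions(k, 5);
        else if (kind == 2) Is_ext += inductions(k, 5);
        else suppress = inductions(k, 5);
      }
      I_dend *= (1.0 - suppress);

      if (s == 0) {
        nov_lap[lap] = n;
        Id_lap[lap] = I_dend;
        Is_lap[lap] = I_soma;
      }

      // input rates
      double syn = 0;
      for (int j = 0; j < n_pre; ++j) {
        double d = std::fabs(p - centers[j]);
        if (d > L - d) d = L - d;
        double r = lap_gain[j] * A * std::exp(-d * d / (2 * sig * sig)) +
                   lap_off[j] + input_novelty_coef * n;
        if (r < 0) r = 0;
        R[j] = r;
        syn += w[j] * r;
      }

      const double p_dend = syn - I_dend + Id_ext;
      const double E = Eint + Is_ext;
      const double V = E - I_soma;
      const double gate = !gate_enabled ? 1.0
                          : (gate_strict ? (V > th_prop ? 1.0 : 0.0)
                                         : (V >= th_prop ? 1.0 : 0.0));
      double gd;
      if (linear) {
        const double th = std::tanh(p_dend / I0lin);
        gd = (a1 + a2) * (th > 0 ? th : 0);
      } else {
        const double th = std::tanh(p_dend / I0);
        gd = a1 * (th > 0 ? th : 0) +
             a2 * 0.5 * (std::tanh(2 * (p_dend - I0)) + 1);
      }
      double target_s = gate * r_d + E - I_soma - Nth;
      if (target_s < 0) target_s = 0;

      // record start-of-step state at the current position
      const int b = std::min((int)(p / binw), n_bins - 1);
      map_d(lap, b) += r_d;
      map_s(lap, b) += r_s;
      map_u(lap, b) += gate * r_d + V;
      map_p(lap, b) += p_dend;
      map_cnt(lap, b) += 1;
      acc_d += r_d;
      acc_s += r_s;

      // dendritic-spike detection: upward crossing of p_dend through I0
      if (s == 0 && lap == 0) prev_pdend = p_dend;
      if (p_dend > I0 && prev_pdend <= I0) {
        spikes[lap] += 1;
        if (first_spike_lap == 0) first_spike_lap = abs_lap;
      }
      prev_pdend = p_dend;

      // synchronous update from start-of-step state
      const double aa = dt / tau0;
      if (plasticity) {
        double sumw_old = 0;
        for (int j = 0; j < n_pre; ++j) sumw_old += w[j];
        const double hom = eta_homeo * (sumw_old - th_homeo);
        for (int j = 0; j < n_pre; ++j) {
          w[j] += dt * (eta_ex * r_d * R[j] - hom);
          if (w[j] > w_max) w[j] = w_max;
          if (clip_w && w[j] < 0) w[j] = 0;
        }
      }
      r_d += aa * (gd - r_d);
      if (r_d < 0) r_d = 0;
      r_s += aa * (target_s - r_s);
      if (r_s < 0) r_s = 0;

      if (!(std::isfinite(r_d) && std::isfinite(r_s)) || r_d > 1e6 ||
          r_s > 1e6) {
        stop("numerical blow-up at t = %f ms (lap %d)", t, abs_lap);
      }
      for (int j = 0; j < n_pre; ++j)
        if (!std::isfinite(w[j]) || std::fabs(w[j]) > 1e6)
          stop("numerical blow-up in weights at t = %f ms", t);
    }

    for (int b = 0; b < n_bins; ++b) {
      if (map_cnt(lap, b) == 0)
        stop("empty spatial bin: dt * v exceeds the bin width");
      map_d(lap, b) /= map_cnt(lap, b);
      map_s(lap, b) /= map_cnt(lap, b);
      map_u(lap, b) /= map_cnt(lap, b);
      map_p(lap, b) /= map_cnt(lap, b);
    }
    mean_d[lap] = acc_d / steps;
    mean_s[lap] = acc_s / steps;
  }

  for (int j = 0; j < n_pre; ++j) w_snap(n_laps, j) = w[j];
  r_snap(n_laps, 0) = r_d;
  r_snap(n_laps, 1) = r_s;

  return List::create(
      _["map_dend"] = map_d, _["map_soma"] = map_s,
      _["map_sub"] = map_u, _["map_pdend"] = map_p,
      _["mean_dend"] = mean_d, _["mean_soma"] = mean_s,
      _["novelty"] = nov_lap, _["I_dend"] = Id_lap, _["I_soma"] = Is_lap,
      _["w_snapshots"] = w_snap, _["r_snapshots"] = r_snap,
      _["dend_spikes"] = spikes, _["first_spike_lap"] = first_spike_lap,
      _["t_end"] = t0 + (double)n_laps * steps * dt);
}
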