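#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop motor-unit-pool contraction.
//
// Per-sample loop: a PID controller updates a scalar excitatory drive from the
// force error; units whose recruitment threshold is at or below the drive fire
// as renewal processes whose mean rate grows linearly with the excess drive
// (capped at peak_rate), with Gaussian interspike-interval jitter; each
// discharge adds a critically-damped twitch (A * (t/Tc) * exp(1 - t/Tc)) to
// the force buffer. Force is expressed in % MVC via fmax, the analytic
// steady-state force at maximal drive.
//
// drive_in of length = target length switches to open-loop mode (PID bypassed)
// so the twitch superposition can be checked against an analytic oracle.
//
// Uses R's RNG (norm_rand), so results are reproducible under set.seed().
// [[Rcpp::export]]
List contraction_loop(NumericVector target, double dt,
                      NumericVector thresholds, double min_rate,
                      double rate_gain, double peak_rate,
                      NumericVector twitch_amp, NumericVector twitch_tc,
                      double isi_cov, double kp, double ki, double kd,
                      NumericVector drive_in, double fmax,
                      double drive_max, double f_limit) {
  const int T = target.size();
  const int n = thresholds.size();
  const bool open_loop = drive_in.size() == T;

  // precompute twitch kernels (support 6 * Tc)
  std::vector< std::vector<double> > kern(n);
  int max_k = 0;
  for (int i = 0; i < n; ++i) {
    int nk = (int)std::ceil(6.0 * twitch_tc[i] / dt);
    kern[i].resize(nk);
    for (int j = 0; j < nk; ++j) {
      double t = (j + 1) * dt;
      kern[i][j] = twitch_amp[i] * (t / twitch_tc[i]) *
                   std::exp(1.0 - t / twitch_tc[i]);
    }
    if (nk > max_k) max_k = nk;
  }

  std::vector<double> force(T + max_k + 1, 0.0);
  NumericVector force_pct(T), drive_trace(T);
  std::vector< std::vector<int> > spikes(n);
  // earliest permitted next discharge per unit (samples). Persists across
  // de-recruitment so drive fluctuations around a unit's threshold cannot
  // trigger immediate re-firing; a freshly recruited unit whose interval has
  // elapsed fires at the recruitment instant.
  std::vector<double> next_spike(n, 0.0);
  double drive = 0.0, e_prev = 0.0, e_prev2 = 0.0;
  bool diverged = false;

  RNGScope scope;

  for (int t = 0; t < T; ++t) {
    double f_now = 100.0 * force[t] / fmax;
    if (open_loop) {
      drive = drive_in[t];
    } else {
      double e = target[t] - f_now;
      drive += kp * (e - e_prev) + ki * e * dt +
               (t >= 2 ? kd * (e - 2.0 * e_prev + e_prev2) / dt : 0.0);
      e_prev2 = e_prev;
      e_prev = e;
      if (drive < 0.0) drive = 0.0;
      if (drive > drive_max) drive = drive_max;
    }
    drive_trace[t] = drive;

    for (int i = 0; i < n; ++i) {
      bool active = thresholds[i] <= drive;
      if (!active) continue;
      if ((double)t >= next_spike[i]) {
        spikes[i].push_back(t + 1);                   // 1-based sample index
        const std::vector<double>& k = kern[i];
        for (size_t j = 0; j < k.size(); ++j) force[t + 1 + j] += k[j];
        double rate = min_rate + rate_gain * (drive - thresholds[i]);
        if (rate > peak_rate) rate = peak_rate;
        double isi = 1.0 / rate;
        if (isi_cov > 0.0) {
          double z = norm_rand();
          if (z > 3.0) z = 3.0;
          if (z < -3.0) z = -3.0;
          isi *= (1.0 + isi_cov * z);
        }
        if (isi < 0.25 / peak_rate) isi = 0.25 / peak_rate;
        next_spike[i] = (double)t + isi / dt;
      }
    }

    force_pct[t] = f_now;
    if (f_now > f_limit) { diverged = true; break; }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = IntegerVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["spikes"] = sp, _["force"] = force_pct,
                      _["drive"] = drive_trace, _["diverged"] = diverged);
}
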