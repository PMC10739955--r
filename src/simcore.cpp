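#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of the adaptive LIF network with context,
// foot-shock and hazelnut inputs, plus the delayed plasticity rules.
//
// Reduction used for the context pathway: all n_context channels share the
// same Poisson rate and synaptic kernel, initial per-channel weights are a
// uniform split of each neuron's weight sum, and the learning increment is
// channel-uniform; the weight matrix therefore stays rank-one and only the
// per-neuron weight sum and the pooled filtered context train R(t) are
// evolved.  I_context_i = (context_gain / n_context) * omega_sum_i * R(t).

static inline double fs_drive(double t_s, const std::vector<double> &fs) {
  double v = 0.0;
  for (size_t i = 0; i < fs.size(); ++i) {
    double d = t_s - fs[i];
    if (std::fabs(d) < 8.0) v += std::exp(-d * d);
  }
  return v;
}

// [[Rcpp::export(name = ".simcore")]]
List simcore(List par, List proto, NumericVector omega_sum0,
             NumericVector fs_w, NumericVector nut_w,
             int sample_every, int omega_every) {
  const double tau_m   = par["tau_m"];        // ms
  const double v_reset = par["v_reset"];      // mV
  const double v_th    = par["v_threshold"];  // mV
  const double i_bias  = par["i_bias"];       // pA
  const double d_adapt = par["d"];            // pA
  const double tau_w   = par["tau_w"];        // ms
  const int    n       = par["n_neurons"];
  const int    n_ctx   = par["n_context"];
  const double tdc     = par["tau_d_context"]; // ms
  const double trc     = par["tau_r_context"]; // ms
  const double eps     = par["epsilon"];       // 1/s
  const double Omega   = par["omega_ceiling"];
  const double tau_d   = par["tau_d"];         // ms (r_slow decay)
  const double tau_r   = par["tau_r"];         // ms (r_slow rise)
  const double tau_om  = par["tau_omega"];     // s
  const double sigma   = par["noise_sd"];      // mV, stationary sd of V noise
  const double r_thr   = par["r_thresh"];
  const double nut_thr = par["nut_thresh"];
  const double gain    = par["context_gain"];
  const double dt      = par["dt"];            // ms
  const std::string rule = as<std::string>(par["rule"]); // two_factor|one_factor|none

  const double total_s   = proto["total_duration_s"];
  NumericMatrix novel    = proto["novel_intervals_s"]; // k x 2
  const double rate_nov  = proto["context_rate_novel_hz"];
  const double rate_home = proto["context_rate_home_hz"];
  NumericVector fs_times = proto["fs_times_s"];
  const double nut_time  = proto["nut_time_s"]; // NA if absent

  std::vector<double> fsv(fs_times.begin(), fs_times.end());
  const bool has_nut = !NumericVector::is_na(nut_time);
  const int rcode = (rule == "two_factor") ? 1 :
                    (rule == "one_factor") ? 2 : 0;

  const long n_steps = (long)std::llround(total_s * 1000.0 / dt);
  const double dt_s  = dt / 1000.0;
  const double alpha = dt / tau_m;
  const double beta  = sigma * std::sqrt(2.0 * alpha - alpha * alpha);

  // exact exponential decay factors for the synaptic filters
  const double k_cd = std::exp(-dt / tdc), k_cr = std::exp(-dt / trc);
  const double k_sd = std::exp(-dt / tau_d), k_sr = std::exp(-dt / tau_r);

  std::vector<double> V(n, v_reset), w(n, 0.0);
  std::vector<double> ed(n, 0.0), er(n, 0.0);           // r_slow states
  std::vector<double> om(omega_sum0.begin(), omega_sum0.end());
  std::vector<double> a(om);                             // a starts at omega
  double ced = 0.0, cer = 0.0;                           // pooled context filter

  std::vector< std::vector<double> > spikes(n);

  const long n_samp = n_steps / sample_every;
  NumericMatrix r_slow_out(n, n_samp);
  NumericVector r_slow_t(n_samp);
  NumericVector ctx_out(n_samp);
  const long n_om = n_steps / omega_every;
  NumericMatrix omega_out(n, n_om);
  NumericVector omega_t(n_om);

  RNGScope scope;
  long si = 0, oi = 0;

  for (long step = 0; step < n_steps; ++step) {
    const double t_s = step * dt_s;

    // context input: pooled Poisson spikes over all channels
    double rate = rate_home;
    for (int k = 0; k < novel.nrow(); ++k)
      if (t_s >= novel(k, 0) && t_s < novel(k, 1)) { rate = rate_nov; break; }
    double lam = n_ctx * rate * dt_s;
    double k_sp = (lam > 0.0) ? R::rpois(lam) : 0.0;
    ced = ced * k_cd + k_sp;
    cer = cer * k_cr + k_sp;
    const double R_ctx = ced - cer;

    const double fs_t  = fsv.empty() ? 0.0 : fs_drive(t_s, fsv);
    double nut_t = 0.0;
    if (has_nut) {
      double dn = t_s - nut_time;
      nut_t = std::exp(-dn * dn / 1.0e4);
    }
    const bool nut_gate = has_nut && (nut_t > nut_thr);

    for (int i = 0; i < n; ++i) {
      // synaptic filter decay (exact), membrane + adaptation (forward Euler)
      ed[i] *= k_sd; er[i] *= k_sr;
      const double r_slow = ed[i] - er[i];

      const double i_syn = (gain / n_ctx) * om[i] * R_ctx +
                           fs_w[i] * fs_t + nut_w[i] * nut_t;
      double dV = alpha * (-V[i] + i_bias + i_syn - w[i]);
      if (beta > 0.0) dV += beta * norm_rand();
      V[i] += dV;
      w[i] -= dt * w[i] / tau_w;

      if (V[i] >= v_th) {
        spikes[i].push_back((step + 1) * dt);  // ms
        V[i] = v_reset;
        w[i] += d_adapt;
        ed[i] += 1.0; er[i] += 1.0;
      }
      if (!std::isfinite(V[i]))
        stop("integration failure: non-finite voltage for neuron %d at t = %.3f s",
             i + 1, t_s);

      // plasticity (a integrates; omega relaxes toward a with tau_omega)
      if (rcode == 1) {
        if (r_slow > r_thr)
          a[i] += dt_s * eps * (Omega - om[i]) * r_slow;
      } else if (rcode == 2) {
        if (nut_gate)
          a[i] += dt_s * eps * (Omega - om[i]);
      }
      om[i] += dt_s / tau_om * (a[i] - om[i]);
    }

    if ((step + 1) % sample_every == 0 && si < n_samp) {
      for (int i = 0; i < n; ++i) r_slow_out(i, si) = ed[i] - er[i];
      r_slow_t[si] = (step + 1) * dt_s;
      ctx_out[si] = R_ctx;
      ++si;
    }
    if ((step + 1) % omega_every == 0 && oi < n_om) {
      for (int i = 0; i < n; ++i) omega_out(i, oi) = om[i];
      omega_t[oi] = (step + 1) * dt_s;
      ++oi;
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = wrap(spikes[i]);

  return List::create(
    _["spike_times_ms"] = sp,
    _["r_slow"] = r_slow_out, _["r_slow_time_s"] = r_slow_t,
    _["context_trace"] = ctx_out,
    _["omega_sum"] = omega_out, _["omega_time_s"] = omega_t,
    _["omega_final"] = wrap(om), _["a_final"] = wrap(a));
}
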