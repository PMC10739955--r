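# Independent reference implementations used as oracles.

# Hand-derived Euler step of the two-factor rule (scalar weight-sum level):
# da = dt_s * eps * (Omega - omega_sum) * r_slow * H(r_slow - r_thresh)
oracle_two_factor_da <- function(eps, Omega, omega_sum, r_slow, r_thresh,
                                 dt_s) {
  if (r_slow > r_thresh) dt_s * eps * (Omega - omega_sum) * r_slow else 0
}

# One-factor rule: da = dt_s * eps * (Omega - omega_sum) * H(nut - thresh)
oracle_one_factor_da <- function(eps, Omega, omega_sum, nut, nut_thresh,
                                 dt_s) {
  if (nut > nut_thresh) dt_s * eps * (Omega - omega_sum) else 0
}

# Plain-R forward-Euler integration of a single adaptive LIF neuron with
# given deterministic drive (function of time in seconds), mirroring the
# published update scheme.  Used to cross-check the compiled network core
# on noiseless scenarios, including plasticity.
oracle_lif <- function(par, drive_fun, duration_s, rule = "none",
                       nut_fun = NULL) {
  dt <- par$dt; n_steps <- round(duration_s * 1000 / dt)
  dt_s <- dt / 1000
  k_sd <- exp(-dt / par$tau_d); k_sr <- exp(-dt / par$tau_r)
  V <- par$v_reset; w <- 0; ed <- 0; er <- 0
  om <- par$omega_sum0; a <- om
  spikes <- numeric(0)
  for (step in seq_len(n_steps)) {
    t_s <- (step - 1) * dt_s
    ed <- ed * k_sd; er <- er * k_sr
    r_slow <- ed - er
    V <- V + dt / par$tau_m * (-V + par$i_bias + drive_fun(t_s) - w)
    w <- w - dt * w / par$tau_w
    if (V >= par$v_threshold) {
      spikes <- c(spikes, step * dt)
      V <- par$v_reset; w <- w + par$d
      ed <- ed + 1; er <- er + 1
    }
    if (rule == "two_factor") {
      a <- a + oracle_two_factor_da(par$epsilon, par$omega_ceiling, om,
                                    r_slow, par$r_thresh, dt_s)
    } else if (rule == "one_factor") {
      a <- a + oracle_one_factor_da(par$epsilon, par$omega_ceiling, om,
                                    nut_fun(t_s), par$nut_thresh, dt_s)
    }
    om <- om + dt_s / par$tau_omega * (a - om)
  }
  list(spikes_ms = spikes, omega = om, a = a)
}

# Closed-form LIF inter-spike interval under constant suprathreshold drive
oracle_isi_ms <- function(tau_m, i_total, v_reset, v_th) {
  tau_m * log((i_total - v_reset) / (i_total - v_th))
}

# Random photometry session spec in the operating range of the recordings
# the generator emulates (900 s at 100 Hz, transients confined to the
# middle so the head/tail fit windows stay clean).
random_photometry_case <- function(seed) {
  set.seed(seed)
  baseline <- runif(1, 5, 20)
  n_ev <- sample(1:3, 1)
  list(duration_s = 900, rate_hz = 100,
       bleach_coeffs_sig = c(runif(1, 2e-8, 1e-7), runif(1, -4e-4, -2e-4), 1),
       bleach_coeffs_ref = c(runif(1, 2e-8, 1e-7), runif(1, -4e-4, -2e-4),
                             runif(1, 0.8, 1.2)),
       baseline_level = baseline,
       event_times_s = sample(c(360, 410, 460, 510), n_ev) +
         runif(n_ev, -5, 5),
       event_amplitudes = runif(n_ev, 0.05, 0.15) * baseline,
       event_decay_s = 2,
       context_step = c(320, 560, runif(1, 0.02, 0.05) * baseline),
       noise_sd = runif(1, 0.001, 0.002) * baseline,
       seed = seed)
}

# Matched-filter estimate of a single event amplitude from a de-trended
# trace: least-squares fit of the known exponential kernel on a window
# after the event, with the local pre-event level subtracted.
estimate_event_amplitude <- function(values, time_s, t_event, decay_s) {
  pre <- values[time_s >= t_event - 5 & time_s < t_event - 0.2]
  win <- time_s >= t_event & time_s <= t_event + 3 * decay_s
  kern <- exp(-(time_s[win] - t_event) / decay_s)
  y <- values[win] - median(pre)
  sum(y * kern) / sum(kern^2)
}

run_sim <- function(mode, seed, time_scale = 4, ...) {
  simulate_network(network_params(mode, ...),
                   build_protocol(mode, time_scale = time_scale),
                   seed = seed)
}
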