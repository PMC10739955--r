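test_that("protocols carry the published timeline", {
  p <- build_protocol("aversive")
  expect_length(p$fs_times_s, 10)
  expect_equal(p$fs_times_s, seq(900, 1170, by = 30))
  expect_equal(unique(diff(p$fs_times_s)), 30)
  expect_equal(p$total_duration_s, 2190)
  expect_equal(p$novel_intervals_s[1, ], c(500, 1290), ignore_attr = TRUE)

  ctl <- build_protocol("control")
  expect_length(ctl$fs_times_s, 0)
  expect_true(is.na(ctl$nut_time_s))

  ap <- build_protocol("appetitive")
  expect_equal(ap$nut_time_s, 930)
  expect_length(ap$fs_times_s, 0)
})

test_that("invalid protocols are rejected", {
  expect_error(build_protocol("aversive", fs_window_s = c(100, 400)),
               "novel-context")
  expect_error(build_protocol("appetitive", nut_time_s = 100),
               "novel-context")
  expect_error(build_protocol("control", total_duration_s = -1), "positive")
  expect_error(network_params("aversive", v_reset = -20), "v_threshold")
  expect_error(network_params("aversive", frobnicate = 1), "unknown")
})

test_that("stimulus waveforms match their closed forms", {
  fs <- seq(900, 1170, by = 30)
  expect_equal(fs_current(900, fs), 1.0, tolerance = 1e-12)
  expect_lt(fs_current(915, fs), 1e-30)              # midway between shocks
  expect_equal(fs_current(901, fs), exp(-1), tolerance = 1e-12)
  expect_equal(fs_current(905, fs), exp(-25), tolerance = 1e-6)

  expect_equal(nut_current(930, 930), 1.0)
  expect_equal(nut_current(1030, 930), exp(-1))
  expect_lt(nut_current(930 + 1e4, 930), 1e-300)
  expect_equal(nut_current(5, NA_real_), 0)
})

test_that("the context filter has the double-exponential shape and mean", {
  # closed form: peak of exp(-t/20) - exp(-t/2) at (20*2/18)*log(10) ms
  tt <- seq(0, 60, by = 0.01)
  r <- crhmem:::double_exp_filter(0, tt, 20, 2)
  t_peak <- (20 * 2 / 18) * log(10)
  expect_equal(tt[which.max(r)], t_peak, tolerance = 0.01)
  expect_equal(max(r), exp(-t_peak / 20) - exp(-t_peak / 2),
               tolerance = 1e-4)

  # pooled Poisson train at 8 Hz/channel: time-average of the filtered
  # trace is n_context * rate * (tau_d - tau_r) within 5%
  pr <- build_protocol("control", total_duration_s = 200,
                       novel_intervals_s = rbind(c(0, 200)))
  pa <- network_params("control", n_neurons = 1L, n_context = 200L,
                       noise_sd = 0)
  sim <- simulate_network(pa, pr, seed = 42)
  expect_equal(mean(sim$context_trace), 200 * 8 * (0.020 - 0.002),
               tolerance = 0.05)
})

test_that("a subthreshold neuron never fires", {
  # all inputs off: V relaxes to I_bias = -41 mV, below the -40 mV threshold
  pr <- build_protocol("control", total_duration_s = 60,
                       novel_intervals_s = rbind(c(0, 60)),
                       context_rate_novel_hz = 0, context_rate_home_hz = 0)
  sim <- simulate_network(network_params("control", n_neurons = 5L,
                                         noise_sd = 0), pr, seed = 1)
  expect_equal(sum(lengths(sim$spike_times_ms)), 0)
  expect_equal(max(sim$r_slow), 0)
})

test_that("noiseless LIF spike trains match a plain-R Euler oracle", {
  # constant drive via the bias current; adaptation on; no noise
  pa <- network_params("aversive", n_neurons = 1L, i_bias = -30,
                       noise_sd = 0, d = 5)
  pr <- build_protocol("control", total_duration_s = 5,
                       novel_intervals_s = rbind(c(0, 5)),
                       context_rate_novel_hz = 0, context_rate_home_hz = 0)
  sim <- simulate_network(pa, pr, seed = 1)
  orc <- oracle_lif(c(unclass(pa), omega_sum0 = 0),
                    function(t) 0, 5)
  expect_equal(sim$spike_times_ms[[1]], orc$spikes_ms, tolerance = 1e-9)
  expect_gt(length(orc$spikes_ms), 10)
})

test_that("inter-spike intervals match the closed form within one step", {
  for (i_drive in c(-35, -32.5, -30, -27.5, -25, -20)) {
    pa <- network_params("aversive", n_neurons = 1L, i_bias = i_drive,
                         noise_sd = 0, d = 0)
    pr <- build_protocol("control", total_duration_s = 2,
                         novel_intervals_s = rbind(c(0, 2)),
                         context_rate_novel_hz = 0,
                         context_rate_home_hz = 0)
    sim <- simulate_network(pa, pr, seed = 1)
    isi <- diff(sim$spike_times_ms[[1]])
    expect_gt(length(isi), 5)
    expect_equal(length(unique(isi)), 1)   # constant drive, constant ISI
    closed <- oracle_isi_ms(10, i_drive, -65, -40)
    expect_lt(abs(isi[1] - closed), 1.0 + 1e-9)
  }
})

test_that("the two-factor plasticity trajectory matches the R oracle", {
  # one neuron, deterministic: a single strong shock input opens the gate
  pa <- network_params("aversive", n_neurons = 1L, noise_sd = 0,
                       r_thresh = 1, omega_init_max = 0)
  pr <- build_protocol("aversive", total_duration_s = 12,
                       novel_intervals_s = rbind(c(0, 12)),
                       context_rate_novel_hz = 0, context_rate_home_hz = 0,
                       fs_window_s = c(4, 5), fs_spacing_s = 30)
  sim <- simulate_network(pa, pr, seed = 7)
  fs_w <- sim$fs_weights[1]
  orc <- oracle_lif(c(unclass(pa), omega_sum0 = 0),
                    function(t) fs_w * exp(-(t - 4)^2), 12,
                    rule = "two_factor")
  expect_equal(sim$spike_times_ms[[1]], orc$spikes_ms, tolerance = 1e-9)
  expect_gt(orc$a, 0)                       # the gate actually opened
  expect_equal(sim$a_final[1], orc$a, tolerance = 1e-10)
  expect_equal(sim$omega_final[1], orc$omega, tolerance = 1e-10)
})

test_that("the one-factor plasticity trajectory matches the R oracle", {
  pa <- network_params("appetitive", n_neurons = 1L, noise_sd = 0,
                       omega_init_max = 0.5)
  pr <- build_protocol("appetitive", total_duration_s = 400,
                       novel_intervals_s = rbind(c(0, 400)),
                       context_rate_novel_hz = 0, context_rate_home_hz = 0,
                       nut_time_s = 100)
  sim <- simulate_network(pa, pr, seed = 3)
  om0 <- sim$omega_init[1]
  nut_w <- sim$nut_weights[1]
  orc <- oracle_lif(c(unclass(pa), omega_sum0 = om0),
                    function(t) nut_w * exp(-(t - 100)^2 / 1e4), 400,
                    rule = "one_factor",
                    nut_fun = function(t) exp(-(t - 100)^2 / 1e4))
  expect_lt(orc$a, om0)                     # weights driven down
  expect_equal(sim$a_final[1], orc$a, tolerance = 1e-10)
  expect_equal(sim$omega_final[1], orc$omega, tolerance = 1e-10)
})

test_that("single-step rule updates equal the hand-evaluated values", {
  # frozen hand computations of the Euler updates at dt = 1 ms
  expect_equal(oracle_two_factor_da(0.014, 0.0031, 0, 2, 1, 0.001),
               8.68e-8)
  expect_equal(oracle_two_factor_da(0.014, 0.0031, 0.0031, 5, 1, 0.001),
               0)                            # at the ceiling
  expect_equal(oracle_two_factor_da(0.014, 0.0031, 0, 0.5, 1, 0.001),
               0)                            # gate closed
  expect_equal(oracle_two_factor_da(0.014, 0.0031, 0, 1, 1, 0.001),
               0)                            # H(0) = 0: ties do not gate
  expect_equal(oracle_one_factor_da(2e-6, -1, 0.5, 0.9, 0.5, 0.001),
               -3e-9)
  expect_equal(oracle_one_factor_da(2e-6, -1, 0.5, 0.3, 0.5, 0.001), 0)
})

test_that("simulations are reproducible and epoch means are exact", {
  pa <- network_params("aversive", n_neurons = 10L)
  pr <- build_protocol("aversive", time_scale = 20)
  s1 <- simulate_network(pa, pr, seed = 5)
  s2 <- simulate_network(pa, pr, seed = 5)
  expect_identical(s1$spike_times_ms, s2$spike_times_ms)
  expect_identical(s1$epoch_means, s2$epoch_means)

  # epoch_means: constant, single-sample and ramp windows
  fake <- s1
  fake$r_slow <- matrix(rep(3, 100), 1)
  fake$r_slow_time_s <- seq(0.1, 10, by = 0.1)
  expect_equal(epoch_means(fake, rbind(c(0, 10)))[1, 1], 3)
  expect_equal(epoch_means(fake, rbind(c(0.95, 1.05)))[1, 1], 3)
  fake$r_slow <- matrix(seq(0, 1, length.out = 100), 1)
  expect_equal(epoch_means(fake, rbind(c(0, 10)))[1, 1], 0.5,
               tolerance = 0.01)
  expect_error(epoch_means(fake, rbind(c(90, 95))), "empty epoch")
})

test_that("halving the time step changes deterministic epoch means < 5%", {
  # deterministic scenario: suprathreshold bias, no noise, no context
  em <- lapply(c(1, 0.5), function(dt) {
    pa <- network_params("aversive", n_neurons = 1L, i_bias = -38,
                         noise_sd = 0, dt = dt)
    pr <- build_protocol("control", total_duration_s = 30,
                         novel_intervals_s = rbind(c(0, 30)),
                         context_rate_novel_hz = 0,
                         context_rate_home_hz = 0)
    simulate_network(pa, pr, seed = 1)$epoch_means
  })
  expect_equal(em[[1]][1, "home"], em[[2]][1, "home"], tolerance = 0.05)
})

test_that("time-compressed protocols learn the same weights", {
  # the learned weight change is set by absolute gated time under the
  # fixed-width shock gates, so compressing the timeline (and tau_omega)
  # preserves it
  s4 <- run_sim("aversive", seed = 2, time_scale = 4, n_neurons = 30L)
  s8 <- run_sim("aversive", seed = 2, time_scale = 8, n_neurons = 30L)
  d4 <- mean(s4$omega_final - s4$omega_init)
  d8 <- mean(s8$omega_final - s8$omega_init)
  expect_gt(d4, 0)
  expect_equal(d4, d8, tolerance = 0.35)
})
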