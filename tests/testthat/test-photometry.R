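test_that("session construction and trimming", {
  s <- synth_photometry(900, 100, baseline_level = 2)$session
  tr <- trim_session(s)
  expect_equal(diff(range(tr$time_s)), 300 - 0.01)
  expect_equal(min(tr$time_s), 0)
  expect_error(trim_session(synth_photometry(600, 100)$session),
               "not longer")

  # annotations are re-indexed by the trimmed offset
  s2 <- photometry_session(s$time_s, s$signal, s$reference, 100,
                           annotations = data.frame(name = "ctx",
                                                    start_s = 400,
                                                    end_s = 520))
  tr2 <- trim_session(s2)
  expect_equal(tr2$annotations$start_s, 100)
  expect_equal(tr2$annotations$end_s, 220)
})

test_that("polynomial detrending recovers exact and synthetic trends", {
  t <- seq(0, 600, by = 0.01)
  y <- 2e-7 * t^2 - 1e-3 * t + 5
  d <- detrend_polynomial(y, t)
  expect_lt(max(abs(d$values)), 1e-9)
  expect_equal(d$coefficients, c(2e-7, -1e-3, 5), tolerance = 1e-6)

  dc <- detrend_polynomial(rep(4, 100), seq_len(100))
  expect_equal(dc$coefficients[3], 4, tolerance = 1e-8)
  expect_lt(max(abs(dc$values)), 1e-9)

  # synthetic session with a transient outside the fit windows: recovered
  # bleaching coefficients within 1% of the generator truth
  s <- synth_photometry(900, 100, c(1e-7, -1e-3, 1), baseline_level = 10,
                        event_times_s = 450, event_amplitudes = 1,
                        noise_sd = 0.02, seed = 1)
  d <- detrend_polynomial(s$session$signal, s$session$time_s,
                          rbind(c(0, 300), c(600, 900)))
  expect_equal(d$coefficients, s$truth$bleach_coeffs_signal,
               tolerance = 0.01)
  expect_error(detrend_polynomial(1:10, 1:10, rbind(c(20, 30))),
               "underdetermined")
})

test_that("reference fitting inverts affine maps", {
  set.seed(1)
  x <- rnorm(1000)
  f <- fit_reference(x, x)
  expect_equal(f$alpha, 1, tolerance = 1e-12)
  expect_equal(f$beta, 0, tolerance = 1e-12)

  ref <- 2 * x - 3
  f2 <- fit_reference(ref, x)
  expect_equal(f2$alpha, 0.5, tolerance = 1e-12)
  expect_equal(f2$beta, 1.5, tolerance = 1e-12)

  # uncorrelated channels: alpha ~ 0, fitted trace ~ mean(signal)
  y <- rnorm(2000); z <- rnorm(2000)
  f3 <- fit_reference(z, y)
  expect_lt(abs(f3$alpha), 0.1)
  expect_equal(mean(f3$fitted), mean(y), tolerance = 1e-10)
  expect_error(fit_reference(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("delta-F cancels common-mode artifacts and recovers events", {
  expect_equal(delta_f(1:5, 1:5), rep(0, 5))

  # noiseless common-mode motion, matched channels: exact cancellation
  s <- synth_photometry(900, 100, c(0, 0, 1), baseline_level = 10,
                        motion_times_s = c(200, 700),
                        motion_amplitudes = c(3, -2))
  f <- fit_reference(s$session$reference, s$session$signal)
  d <- delta_f(s$session$signal, f$fitted)
  expect_lt(max(abs(d)), 1e-9)

  # full chain on a noisy bleached session: event amplitude within 5%
  s <- synth_photometry(900, 100, c(1e-7, -8e-4, 1),
                        bleach_coeffs_ref = c(8e-8, -6e-4, 0.9),
                        baseline_level = 10, event_times_s = c(400, 480),
                        event_amplitudes = c(1, 0.8), event_decay_s = 2,
                        noise_sd = 0.02, seed = 2)
  fw <- rbind(c(0, 300), c(600, 900))
  t <- s$session$time_s
  ds <- detrend_polynomial(s$session$signal, t, fw)
  dr <- detrend_polynomial(s$session$reference, t, fw)
  fr <- fit_reference(dr$values, ds$values)
  d <- delta_f(ds$values, fr$fitted)
  for (k in 1:2) {
    est <- estimate_event_amplitude(d, t, s$truth$event_times_s[k], 2)
    expect_equal(est, s$truth$event_amp_delta_f[k], tolerance = 0.05)
  }
})

test_that("dF/F normalizes by the fitted reference", {
  set.seed(3)
  ref <- 10 + rnorm(500, 0, 0.5)
  expect_equal(dff(ref, ref)$dff, rep(0, 500), tolerance = 1e-10)
  # a static channel scaling is absorbed by the polynomial map: dF/F stays 0
  expect_equal(dff(1.1 * ref, ref)$dff, rep(0, 500), tolerance = 1e-10)

  # 5% transient on matched bleach: dff peak 0.05 within 10%
  s <- synth_photometry(900, 100, c(1e-7, -1e-3, 1), baseline_level = 10,
                        event_times_s = 450, event_amplitudes = 0.5,
                        event_decay_s = 2, noise_sd = 0.01, seed = 4)
  out <- dff(s$session$signal, s$session$reference)
  t <- s$session$time_s
  est <- estimate_event_amplitude(out$dff, t, 450, 2)
  expect_equal(est, 0.05, tolerance = 0.1)
  expect_error(dff(rnorm(100), rnorm(100, 0, 10)), "non-positive")
})

test_that("z-scoring follows the n-1 convention and day-1 sd source", {
  v <- c(0, 0, 1, 1, 1.0774)
  zs <- zscore_trace(v, 1:4)
  expect_equal(zs$f0, 0.5)
  expect_equal(zs$sigma, sd(c(0, 0, 1, 1)))
  expect_equal(zs$z[5], 1.0, tolerance = 1e-3)

  # trace equal to its baseline mean everywhere -> zeros
  zz <- zscore_trace(rep(3, 50), 1:10, sd_value = 2)
  expect_equal(zz$z, rep(0, 50))

  # day-1 sd twice the same-day sd halves the z magnitudes
  set.seed(5)
  v2 <- rnorm(1000)
  same <- zscore_trace(v2, 1:200)
  cross <- zscore_trace(v2, 1:200, sd_value = 2 * same$sigma)
  expect_equal(cross$z, same$z / 2)
  expect_error(zscore_trace(rep(1, 10), 1:5), "zero")

  # z-scoring the baseline window itself: mean 0 exactly, sd 1 same-day
  zb <- zscore_trace(v2, 1:200)
  expect_equal(mean(zb$z[1:200]), 0, tolerance = 1e-12)
  expect_equal(sd(zb$z[1:200]), 1, tolerance = 1e-12)
})

test_that("epoch means are exact on constant, single-sample and ramps", {
  t <- seq(0, 100, by = 0.1)
  expect_equal(epoch_mean(rep(2, length(t)), t, c(10, 40)), 2)
  expect_equal(epoch_mean(seq_along(t), t, c(50, 50)), which(t == 50))
  expect_equal(epoch_mean(t / 100, t, c(0, 100)), 0.5, tolerance = 1e-3)
  expect_error(epoch_mean(1:10, 1:10, c(20, 30)), "empty")
})

test_that("the pipeline recovers amplitudes across randomized sessions", {
  # 20 randomized specs here; the full 100-spec sweep runs in the
  # acceptance suite
  for (k in 1:20) {
    cs <- random_photometry_case(k)
    s <- do.call(synth_photometry, cs)
    t <- s$session$time_s
    fw <- rbind(c(0, 300), c(600, 900))
    ds <- detrend_polynomial(s$session$signal, t, fw)
    dr <- detrend_polynomial(s$session$reference, t, fw)
    expect_equal(ds$coefficients, s$truth$bleach_coeffs_signal,
                 tolerance = 0.01)
    fr <- fit_reference(dr$values, ds$values)
    d <- delta_f(ds$values, fr$fitted)
    i <- which.max(s$truth$event_amp_delta_f)
    est <- estimate_event_amplitude(d, t, s$truth$event_times_s[i],
                                    cs$event_decay_s)
    expect_equal(est, s$truth$event_amp_delta_f[i], tolerance = 0.05)
  }
})

test_that("photometry_process composes the chain", {
  s <- synth_photometry(1500, 100, c(1e-7, -4e-4, 1), baseline_level = 10,
                        context_step = c(700, 900, 0.5), noise_sd = 0.02,
                        seed = 6)
  pt <- photometry_process(s$session, "zscore", trim_s = 300)
  expect_s3_class(pt, "processed_trace")
  expect_length(pt$values, length(s$session$signal) - 2 * 30000)
  # context elevation visible in z units
  mid <- epoch_mean(pt$values, pt$time_s, c(420, 580))
  base <- epoch_mean(pt$values, pt$time_s, c(0, 180))
  expect_gt(mid, base + 3)
  expect_warning(photometry_process(
    synth_photometry(300, 100, baseline_level = 2)$session, "delta_f"),
    "full trace")
})
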