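#' Parameters for the CRH network simulation
#'
#' Returns the full parameter set for the adaptive leaky integrate-and-fire
#' network, preloaded with the published defaults and adjusted for the
#' requested condition.  The aversive condition uses the two-factor delayed
#' learning rule (`epsilon` = 0.014 s^-1, weight ceiling `omega_ceiling` =
#' 0.0031); the appetitive condition uses the one-factor rule
#' (`epsilon` = 2e-6 s^-1, `omega_ceiling` = -1); the control condition keeps
#' the two-factor rule but the protocol carries no foot shocks.
#'
#' @param mode one of `"aversive"`, `"appetitive"`, `"control"`.  The presets
#'   `fs_table1`, `nutella_table1` and `control` correspond to these three
#'   modes with all defaults.
#' @param ... named overrides for any parameter listed below.
#'
#' @details Fixed defaults: membrane time constant `tau_m` 10 ms, `v_reset`
#'   -65 mV, `v_threshold` -40 mV, bias current `i_bias` -41 pA, adaptation
#'   increment `d` 20 pA with time constant `tau_w` 100 ms, `n_neurons` 100,
#'   `n_context` 1000 context channels filtered with decay `tau_d_context`
#'   20 ms / rise `tau_r_context` 2 ms, slow calcium-proxy filter `tau_d` 1 s
#'   / `tau_r` 100 ms, weight relaxation `tau_omega` 400 s, foot-shock weights
#'   Normal(`fs_weight_mean` = 2, `fs_weight_sd` = 1), hazelnut weights
#'   Uniform(`nut_weight_low` = -0.09, `nut_weight_high` = 0.01), Euler step
#'   `dt` 1 ms.
#'
#'   Free parameters (not fixed by the published model; see the methods
#'   vignette for the rationale behind the defaults): `noise_sd` (stationary
#'   standard deviation, in mV, of the voltage fluctuation induced by the
#'   white-noise current; default 0.3), `r_thresh` (plasticity gate on the
#'   slow rate proxy; default 2), `nut_thresh` (gate on the hazelnut input;
#'   default 0.5), `context_gain` (scales the context current as
#'   `context_gain / n_context * sum(omega_i) * R(t)`; default `n_context`
#'   so that a weight sum at the ceiling produces a context current of order
#'   1 pA), and `omega_init_max` (per-neuron initial weight sums are drawn
#'   Uniform(0, `omega_init_max`); default equals the aversive ceiling
#'   0.0031 in every mode so Pre activity is comparable across conditions).
#'
#' @return an object of class `network_params` (a named list).
#' @seealso [build_protocol()], [simulate_network()]
#' @export
network_params <- function(mode = c("aversive", "appetitive", "control"), ...) {
  mode <- match.arg(mode)
  p <- list(
    mode = mode,
    tau_m = 10, v_reset = -65, v_threshold = -40, i_bias = -41,
    d = 20, tau_w = 100,
    n_neurons = 100L, n_context = 1000L,
    tau_d_context = 20, tau_r_context = 2,
    epsilon = if (mode == "appetitive") 2e-6 else 0.014,
    omega_ceiling = if (mode == "appetitive") -1 else 0.0031,
    tau_d = 1000, tau_r = 100, tau_omega = 400,
    noise_sd = 0.3, r_thresh = 2, nut_thresh = 0.5,
    context_gain = 1000,
    omega_init_max = 0.0031,
    fs_weight_mean = 2, fs_weight_sd = 1,
    nut_weight_low = -0.09, nut_weight_high = 0.01,
    dt = 1,
    rule = if (mode == "appetitive") "one_factor" else "two_factor"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  validate_network_params(p)
  structure(p, class = "network_params")
}

validate_network_params <- function(p) {
  taus <- c("tau_m", "tau_w", "tau_d_context", "tau_r_context",
            "tau_d", "tau_r", "tau_omega")
  for (nm in taus)
    assert_that(p[[nm]] > 0, paste0("'", nm, "' must be positive"))
  assert_that(p$v_reset < p$v_threshold, "'v_reset' must be below 'v_threshold'")
  assert_that(p$dt > 0, "'dt' must be positive")
  assert_that(p$n_neurons >= 1 && p$n_context >= 1,
              "'n_neurons' and 'n_context' must be >= 1")
  assert_that(p$noise_sd >= 0, "'noise_sd' must be non-negative")
  invisible(p)
}

#' Stimulus protocol for the network simulation
#'
#' Builds the experiment timeline: a 2190 s simulation with home-cage
#' context everywhere except two novel-context exposures (500--1290 s and
#' 1790 s to the end), ten 30 s-spaced foot shocks on 900--1200 s in the
#' aversive mode, or a hazelnut-spread presentation centred at 930 s in the
#' appetitive mode.  Context inputs fire at 8 Hz in the novel environment
#' and 1 Hz in the home cage.
#'
#' @param mode `"aversive"`, `"appetitive"` or `"control"`.
#' @param total_duration_s total simulated time, seconds.
#' @param novel_intervals_s two-column matrix of novel-context windows.
#' @param context_rate_novel_hz,context_rate_home_hz per-channel Poisson
#'   rates of the context inputs.
#' @param fs_window_s aversive mode: `c(start, end)` of the shock window.
#' @param fs_spacing_s spacing between consecutive shocks (first shock at
#'   the window start, so the default window yields shocks at 900, 930,
#'   ..., 1170 s: ten events).
#' @param nut_time_s appetitive mode: centre of the hazelnut input.
#' @param time_scale optional compression factor: all protocol times are
#'   divided by `time_scale` (and [simulate_network()] divides `tau_omega`
#'   accordingly) so that shortened runs learn the same weights as the
#'   full-length timeline.  See the methods vignette.
#'
#' @return an object of class `sim_protocol`, including an `epochs` matrix
#'   (rows `home`, `pre`, `fs`/`nut` and `post`) used for epoch averaging.
#' @export
build_protocol <- function(mode = c("aversive", "appetitive", "control"),
                           total_duration_s = 2190,
                           novel_intervals_s = rbind(c(500, 1290),
                                                     c(1790, total_duration_s)),
                           context_rate_novel_hz = 8,
                           context_rate_home_hz = 1,
                           fs_window_s = c(900, 1200),
                           fs_spacing_s = 30,
                           nut_time_s = 930,
                           time_scale = 1) {
  mode <- match.arg(mode)
  novel_intervals_s <- matrix(as.numeric(novel_intervals_s), ncol = 2)
  assert_that(total_duration_s > 0, "total duration must be positive")
  assert_that(time_scale > 0, "'time_scale' must be positive")
  assert_that(all(novel_intervals_s >= 0) &&
                all(novel_intervals_s <= total_duration_s) &&
                all(novel_intervals_s[, 2] > novel_intervals_s[, 1]),
              "novel-context intervals must lie within the total duration")

  fs_times <- numeric(0)
  nut_time <- NA_real_
  if (mode == "aversive") {
    # shocks from the window start, spaced fs_spacing_s, endpoint excluded:
    # [900, 1200] with 30 s pauses yields ten shocks at 900, 930, ..., 1170
    n_fs <- floor((fs_window_s[2] - fs_window_s[1]) / fs_spacing_s - 1e-9) + 1
    fs_times <- fs_window_s[1] + (seq_len(n_fs) - 1) * fs_spacing_s
    in_novel <- vapply(fs_times, function(t)
      any(t >= novel_intervals_s[, 1] & t <= novel_intervals_s[, 2]), logical(1))
    assert_that(all(in_novel),
                "all foot-shock times must fall inside a novel-context interval")
  } else if (mode == "appetitive") {
    nut_time <- nut_time_s
    assert_that(any(nut_time >= novel_intervals_s[, 1] &
                      nut_time <= novel_intervals_s[, 2]),
                "the hazelnut time must fall inside a novel-context interval")
  }

  on1 <- novel_intervals_s[1, ]
  pre_end <- if (mode == "aversive") min(fs_times) else
    if (mode == "appetitive") nut_time else on1[2]
  epochs <- rbind(
    home = c(0, on1[1]),
    pre  = c(on1[1], pre_end),
    post = novel_intervals_s[nrow(novel_intervals_s), ])
  if (mode == "aversive")
    epochs <- rbind(epochs, fs = c(min(fs_times), max(fs_times) + fs_spacing_s))
  if (mode == "appetitive")
    epochs <- rbind(epochs, nut = c(nut_time, on1[2]))
  colnames(epochs) <- c("start_s", "end_s")

  proto <- list(mode = mode,
                total_duration_s = total_duration_s / time_scale,
                novel_intervals_s = novel_intervals_s / time_scale,
                context_rate_novel_hz = context_rate_novel_hz,
                context_rate_home_hz = context_rate_home_hz,
                fs_times_s = fs_times / time_scale,
                nut_time_s = nut_time / time_scale,
                epochs = epochs / time_scale,
                time_scale = time_scale)
  structure(proto, class = "sim_protocol")
}

#' Foot-shock and hazelnut input waveforms
#'
#' `fs_current()` is a sum of unit-height Gaussians of 1 s width centred on
#' the shock times; `nut_current()` is a single Gaussian of width parameter
#' 1e4 s^2 centred on the hazelnut presentation.  Both are unitless drives
#' multiplied by per-neuron random weights inside the simulation.
#'
#' @param t_s time(s), seconds; vectorized.
#' @param fs_times_s foot-shock times, seconds.
#' @param nut_time_s hazelnut presentation time, seconds.
#' @return numeric vector the length of `t_s`.
#' @export
fs_current <- function(t_s, fs_times_s) {
  if (!length(fs_times_s)) return(numeric(length(t_s)))
  vapply(t_s, function(t) sum(exp(-(t - fs_times_s)^2)), numeric(1))
}

#' @rdname fs_current
#' @export
nut_current <- function(t_s, nut_time_s) {
  if (is.na(nut_time_s)) return(numeric(length(t_s)))
  exp(-(t_s - nut_time_s)^2 / 1e4)
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat("Stimulus protocol (", x$mode, " mode)\n", sep = "")
  cat("  total duration:", x$total_duration_s, "s",
      if (x$time_scale != 1) sprintf("(time compressed %gx)", x$time_scale),
      "\n")
  cat("  novel-context intervals:",
      paste(apply(x$novel_intervals_s, 1,
                  function(r) sprintf("[%g, %g]", r[1], r[2])),
            collapse = ", "), "s\n")
  if (length(x$fs_times_s))
    cat("  foot shocks:", length(x$fs_times_s), "events at",
        paste(utils::head(x$fs_times_s, 3), collapse = ", "), "... s\n")
  if (!is.na(x$nut_time_s))
    cat("  hazelnut presentation at", x$nut_time_s, "s\n")
  invisible(x)
}
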