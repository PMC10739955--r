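#' Simulate the CRH network
#'
#' Integrates the network of adaptive leaky integrate-and-fire neurons with
#' the forward Euler method (1 ms step by default) over the protocol
#' timeline, applying the two-factor (aversive/control) or one-factor
#' (appetitive) delayed learning rule.  The per-neuron slow double-
#' exponential spike filter (decay 1 s, rise 100 ms) serves as the simulated
#' calcium indicator; its per-epoch means are the simulation analogue of the
#' per-cell integrated dF/F measured in vivo.
#'
#' @param params a [network_params()] object.
#' @param protocol a [build_protocol()] object.  If the protocol carries a
#'   `time_scale` factor, `tau_omega` is divided by it so the compressed
#'   timeline learns the same weights as the full one.
#' @param seed optional integer seed (both the weight draws and the
#'   integration noise); `NULL` uses the current RNG stream.
#' @param sample_dt_s sampling interval of the stored calcium-proxy traces
#'   (default 0.1 s, the acquisition rate used for imaging analysis).
#' @param omega_dt_s sampling interval of the stored weight-sum traces.
#'
#' @return an object of class `crh_sim` with elements `spike_times_ms`
#'   (list per neuron), `r_slow` (neurons x samples matrix),
#'   `r_slow_time_s`, `omega_sum` trajectory matrix, `fs_weights`,
#'   `nut_weights`, `omega_init` (initial weight sums), `epoch_means`
#'   (neurons x epochs, from the protocol's epoch windows), plus the
#'   resolved `params` and `protocol`.
#' @examples
#' pr <- build_protocol("aversive", time_scale = 10)
#' sim <- simulate_network(network_params("aversive", n_neurons = 20), pr,
#'                         seed = 1)
#' head(sim$epoch_means)
#' @export
simulate_network <- function(params, protocol, seed = NULL,
                             sample_dt_s = 0.1, omega_dt_s = 1) {
  stopifnot(inherits(params, "network_params"),
            inherits(protocol, "sim_protocol"))
  p <- unclass(params)
  if (!is.null(protocol$time_scale) && protocol$time_scale != 1)
    p$tau_omega <- p$tau_omega / protocol$time_scale
  n <- p$n_neurons

  res <- with_seed(seed, {
    omega0 <- runif(n, 0, p$omega_init_max)
    fs_w <- if (length(protocol$fs_times_s))
      rnorm(n, p$fs_weight_mean, p$fs_weight_sd) else numeric(n)
    nut_w <- if (!is.na(protocol$nut_time_s))
      runif(n, p$nut_weight_low, p$nut_weight_high) else numeric(n)
    out <- .simcore(p, protocol, omega0, fs_w, nut_w,
                    sample_every = max(1L, round(sample_dt_s * 1000 / p$dt)),
                    omega_every = max(1L, round(omega_dt_s * 1000 / p$dt)))
    out$omega_init <- omega0
    out$fs_weights <- fs_w
    out$nut_weights <- nut_w
    out
  })

  sim <- structure(
    list(spike_times_ms = res$spike_times_ms,
         r_slow = res$r_slow, r_slow_time_s = res$r_slow_time_s,
         context_trace = res$context_trace,
         omega_sum = res$omega_sum, omega_time_s = res$omega_time_s,
         omega_final = res$omega_final, a_final = res$a_final,
         omega_init = res$omega_init,
         fs_weights = res$fs_weights, nut_weights = res$nut_weights,
         params = params, protocol = protocol, seed = seed),
    class = "crh_sim")
  sim$epoch_means <- epoch_means(sim, protocol$epochs, allow_empty = TRUE)
  sim
}

#' Per-neuron mean of the calcium proxy in time windows
#'
#' @param sim a `crh_sim` object.
#' @param windows two-column matrix (seconds) of window start/end times;
#'   row names label the columns of the result.
#' @param allow_empty return `NA` for windows containing no stored sample
#'   instead of raising an error.
#' @return neurons x windows matrix of arithmetic means of the stored
#'   calcium-proxy samples falling in each window.
#' @export
epoch_means <- function(sim, windows, allow_empty = FALSE) {
  stopifnot(inherits(sim, "crh_sim"))
  windows <- matrix(as.numeric(windows), ncol = 2,
                    dimnames = list(rownames(windows), NULL))
  tt <- sim$r_slow_time_s
  out <- apply(windows, 1, function(w) {
    sel <- tt >= w[1] & tt <= w[2]
    if (!any(sel)) {
      if (allow_empty) return(rep(NA_real_, nrow(sim$r_slow)))
      stop("empty epoch window [", w[1], ", ", w[2], "] s")
    }
    rowMeans(sim$r_slow[, sel, drop = FALSE])
  })
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(out)))
  out
}

#' @export
print.crh_sim <- function(x, ...) {
  n <- length(x$spike_times_ms)
  nsp <- sum(vapply(x$spike_times_ms, length, integer(1)))
  cat("CRH network simulation (", x$protocol$mode, " mode)\n", sep = "")
  cat(sprintf("  %d neurons, %.0f s simulated, %d spikes (%.2f Hz mean rate)\n",
              n, x$protocol$total_duration_s, nsp,
              nsp / n / x$protocol$total_duration_s))
  if (!is.null(x$epoch_means)) {
    cat("  population epoch means of the calcium proxy:\n")
    m <- colMeans(x$epoch_means)
    for (i in seq_along(m))
      cat(sprintf("    %-5s %.3f\n", colnames(x$epoch_means)[i], m[i]))
  }
  invisible(x)
}

#' @export
plot.crh_sim <- function(x, what = c("r_slow", "omega"), ...) {
  what <- match.arg(what)
  if (what == "r_slow") {
    graphics::matplot(x$r_slow_time_s, t(x$r_slow[seq_len(min(10, nrow(x$r_slow))), ]),
                      type = "l", lty = 1, xlab = "time (s)",
                      ylab = "calcium proxy r_slow", ...)
  } else {
    graphics::matplot(x$omega_time_s, t(x$omega_sum[seq_len(min(10, nrow(x$omega_sum))), ]),
                      type = "l", lty = 1, xlab = "time (s)",
                      ylab = expression(Sigma * omega), ...)
  }
  invisible(x)
}
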