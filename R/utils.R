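# internal helpers

# Evaluate `code` under a temporary seed; NULL leaves the caller's RNG
# stream untouched so generators compose like base::simulate().
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# closed-form double-exponential filter response to a spike train,
# r(t) = sum_k exp(-(t - t_k)/tau_d) - exp(-(t - t_k)/tau_r) for t > t_k
double_exp_filter <- function(spike_times, times, tau_d, tau_r) {
  vapply(times, function(t) {
    dt <- t - spike_times
    dt <- dt[dt > 0]
    sum(exp(-dt / tau_d) - exp(-dt / tau_r))
  }, numeric(1))
}
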