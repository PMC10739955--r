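#' Two-channel fiber photometry session
#'
#' Container for a dual-wavelength photometry recording: the
#' calcium-dependent signal channel (465/470 nm excitation) and the
#' calcium-independent isosbestic reference (405 nm), sampled at a common
#' rate, with optional named epoch annotations.
#'
#' @param time_s sample times, seconds.
#' @param signal,reference channel values, arbitrary fluorescence units.
#' @param rate_hz sampling rate.
#' @param annotations optional data.frame with columns `name`, `start_s`,
#'   `end_s`.
#' @return an object of class `photometry_session`.
#' @export
photometry_session <- function(time_s, signal, reference, rate_hz,
                               annotations = NULL) {
  assert_that(length(signal) == length(reference) &&
                length(signal) == length(time_s),
              "channels and time base must have equal length")
  assert_that(rate_hz > 0, "'rate_hz' must be positive")
  if (!is.null(annotations)) {
    stopifnot(all(c("name", "start_s", "end_s") %in% names(annotations)))
    assert_that(all(annotations$start_s >= min(time_s)) &&
                  all(annotations$end_s <= max(time_s) + 1 / rate_hz),
                "annotations must lie within the recording")
  }
  structure(list(time_s = time_s, signal = signal, reference = reference,
                 rate_hz = rate_hz, annotations = annotations),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("Photometry session: %.1f s at %g Hz (%d samples)\n",
              diff(range(x$time_s)) + 1 / x$rate_hz, x$rate_hz,
              length(x$signal)))
  if (!is.null(x$annotations))
    cat("  annotations:", paste(x$annotations$name, collapse = ", "), "\n")
  invisible(x)
}

#' Trim the unstable head and tail of a recording
#'
#' Recordings begin and end with home-cage segments whose first and last
#' five minutes are excluded from analysis (handling and bleaching
#' transients).  Annotations are re-indexed to the trimmed time base.
#'
#' @param session a [photometry_session()].
#' @param head_s,tail_s seconds removed from each end (default 300).
#' @return the interior [photometry_session()], time starting at 0.
#' @export
trim_session <- function(session, head_s = 300, tail_s = 300) {
  stopifnot(inherits(session, "photometry_session"))
  t0 <- min(session$time_s)
  dur <- diff(range(session$time_s)) + 1 / session$rate_hz
  if (dur <= head_s + tail_s)
    stop("recording (", round(dur, 1), " s) is not longer than head + tail (",
         head_s + tail_s, " s)")
  keep <- session$time_s >= t0 + head_s &
    session$time_s < t0 + dur - tail_s
  ann <- session$annotations
  if (!is.null(ann)) {
    ann$start_s <- ann$start_s - head_s
    ann$end_s <- ann$end_s - head_s
    ann <- ann[ann$end_s > 0 & ann$start_s < dur - head_s - tail_s, ,
               drop = FALSE]
  }
  photometry_session(session$time_s[keep] - (t0 + head_s),
                     session$signal[keep], session$reference[keep],
                     session$rate_hz, ann)
}

#' Second-order polynomial bleaching correction
#'
#' Fits `a*t^2 + b*t + c` by least squares using only the samples inside
#' `fit_windows` (by default the first and last five minutes, which avoids
#' contaminating the fit with context-evoked activity), evaluates the
#' polynomial over the whole trace and subtracts it.
#'
#' @param values channel values.
#' @param time_s sample times, seconds.
#' @param fit_windows two-column matrix of `(start, end)` windows used for
#'   fitting; `NULL` fits the full trace.
#' @return list with `values` (detrended trace), `coefficients`
#'   (`c(a, b, c)`) and `trend` (the evaluated polynomial).
#' @export
detrend_polynomial <- function(values, time_s, fit_windows = NULL) {
  assert_that(length(values) == length(time_s),
              "'values' and 'time_s' must have equal length")
  sel <- if (is.null(fit_windows)) rep(TRUE, length(time_s)) else {
    fw <- matrix(as.numeric(fit_windows), ncol = 2)
    Reduce(`|`, lapply(seq_len(nrow(fw)), function(k)
      time_s >= fw[k, 1] & time_s <= fw[k, 2]))
  }
  if (sum(sel) < 3)
    stop("fewer than 3 samples in the fit windows: fit is underdetermined")
  fit <- lm(values[sel] ~ poly(time_s[sel], 2, raw = TRUE))
  cf <- rev(unname(coef(fit)))            # (a, b, c)
  trend <- polyval2(cf, time_s)
  list(values = values - trend, coefficients = cf, trend = trend)
}

#' Least-squares alignment of the isosbestic channel
#'
#' Scales and shifts the 405 nm reference onto the signal channel
#' (`alpha * reference + beta` minimizing squared error), so that the
#' calcium-independent component can be subtracted point by point.
#'
#' @param reference,signal equal-length channel vectors.
#' @return list with `fitted` (scaled reference), `alpha`, `beta`.
#' @export
fit_reference <- function(reference, signal) {
  assert_that(length(reference) == length(signal),
              "channels must have equal length")
  if (stats::var(reference) == 0)
    stop("reference channel has zero variance; cannot fit")
  fit <- lm(signal ~ reference)
  list(fitted = unname(fitted(fit)),
       alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]))
}

#' Motion-corrected fluorescence change
#'
#' Pointwise difference between the calcium-dependent channel and the
#' fitted calcium-independent reference; common-mode motion artifacts
#' cancel.
#'
#' @param signal signal-channel values.
#' @param fitted_reference output of [fit_reference()]`$fitted`.
#' @return numeric vector of the same length.
#' @export
delta_f <- function(signal, fitted_reference) {
  assert_that(length(signal) == length(fitted_reference),
              "channels must have equal length")
  signal - fitted_reference
}

#' Relative fluorescence change via polynomial reference fit
#'
#' Maps the 405 nm channel onto the 465 nm channel with a least-squares
#' second-order polynomial, then computes
#' `(F465 - F_fit405) / F_fit405` pointwise.
#'
#' @param signal,reference channel vectors.
#' @return list with `dff` and `fitted` (the polynomial-mapped reference).
#' @export
dff <- function(signal, reference) {
  assert_that(length(signal) == length(reference),
              "channels must have equal length")
  fit <- lm(signal ~ poly(reference, 2, raw = TRUE))
  f405 <- unname(fitted(fit))
  bad <- which(f405 <= 0)
  if (length(bad))
    stop("fitted reference is non-positive at sample ", bad[1],
         "; dF/F undefined")
  list(dff = (signal - f405) / f405, fitted = f405)
}

#' Baseline z-scoring with a selectable variance source
#'
#' `z = (F - F0) / sigmaF` where `F0` is the mean of the session's own
#' baseline window and `sigmaF` is the baseline standard deviation
#' (sample sd, n-1 denominator) of either the same session or a designated
#' reference day.  Cross-day recordings are scored against the first day's
#' baseline sd so that day-to-day baseline differences do not distort the
#' comparison.
#'
#' @param values trace values.
#' @param baseline logical or integer index of the baseline samples (at
#'   least 2).
#' @param sd_value optional externally supplied `sigmaF` (e.g. the day-1
#'   baseline sd); `NULL` uses the sd of `values[baseline]`.
#' @return list with `z`, `f0`, `sigma`.
#' @export
zscore_trace <- function(values, baseline, sd_value = NULL) {
  base <- values[baseline]
  assert_that(length(base) >= 2, "baseline window must have >= 2 samples")
  f0 <- mean(base)
  sigma <- if (is.null(sd_value)) sd(base) else sd_value
  if (!is.finite(sigma) || sigma == 0)
    stop("baseline standard deviation is zero; z-score undefined")
  list(z = (values - f0) / sigma, f0 = f0, sigma = sigma)
}

#' Mean of a trace in a time window
#'
#' @param values trace values.
#' @param time_s sample times, seconds.
#' @param window `c(start, end)` seconds (default spans 180 s from the
#'   window start, the 3-min analysis segments used throughout).
#' @return scalar mean.
#' @export
epoch_mean <- function(values, time_s, window) {
  sel <- time_s >= window[1] & time_s <= window[2]
  if (!any(sel)) stop("empty epoch window")
  mean(values[sel])
}

#' Full photometry preprocessing chain
#'
#' Convenience wrapper: trims the session, detrends both channels with the
#' second-order polynomial (fit on the first and last `fit_margin_s`
#' seconds), aligns the reference, and returns the motion-corrected trace
#' in the requested flavor.
#'
#' @param session a [photometry_session()].
#' @param method `"zscore"` (delta-F z-scored to a baseline window),
#'   `"delta_f"` or `"dff"`.
#' @param trim_s seconds trimmed from each end before analysis (0 keeps
#'   everything).
#' @param fit_margin_s length of the head/tail windows used for the
#'   bleaching fit; sessions shorter than `2 * fit_margin_s + 60` fall
#'   back to a full-trace fit with a warning.
#' @param baseline_window `c(start, end)` seconds of the baseline used for
#'   z-scoring (defaults to the first 180 s).
#' @param sd_value optional day-1 baseline sd for cross-day scoring.
#' @return an object of class `processed_trace`: list with `time_s`,
#'   `values`, `method` and `baseline_stats`.
#' @export
photometry_process <- function(session,
                               method = c("zscore", "delta_f", "dff"),
                               trim_s = 0, fit_margin_s = 300,
                               baseline_window = NULL, sd_value = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(session, "photometry_session"))
  if (trim_s > 0) session <- trim_session(session, trim_s, trim_s)
  t <- session$time_s
  dur <- diff(range(t))
  fw <- if (dur > 2 * fit_margin_s + 60) {
    rbind(c(min(t), min(t) + fit_margin_s), c(max(t) - fit_margin_s, max(t)))
  } else {
    warning("session too short for head/tail fit windows; ",
            "fitting the bleaching polynomial on the full trace")
    NULL
  }
  baseline_stats <- NULL
  if (method == "dff") {
    out <- dff(session$signal, session$reference)$dff
  } else {
    ds <- detrend_polynomial(session$signal, t, fw)
    dr <- detrend_polynomial(session$reference, t, fw)
    fr <- fit_reference(dr$values, ds$values)
    out <- delta_f(ds$values, fr$fitted)
    if (method == "zscore") {
      bw <- if (is.null(baseline_window)) c(min(t), min(t) + 180) else
        baseline_window
      zs <- zscore_trace(out, t >= bw[1] & t <= bw[2], sd_value)
      out <- zs$z
      baseline_stats <- list(f0 = zs$f0, sigma = zs$sigma, window = bw)
    }
  }
  structure(list(time_s = t, values = out, method = method,
                 baseline_stats = baseline_stats),
            class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("Processed photometry trace (%s): %d samples, range [%.3g, %.3g]\n",
              x$method, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
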