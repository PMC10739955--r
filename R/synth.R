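#' Synthetic dual-channel photometry session
#'
#' Generates a calcium-dependent signal channel and a calcium-independent
#' (isosbestic) reference channel with known ground truth: second-order
#' polynomial bleaching on each channel, a home-cage baseline, sustained
#' context-evoked elevation, exponential-decay calcium transients (signal
#' channel only), motion artifacts shared by both channels, and white
#' noise.  The signal channel is
#' `bleach_sig(t) * (baseline + events + context) + motion + noise`; the
#' reference is `bleach_ref(t) * baseline + gain * motion + noise`.
#'
#' @param duration_s,rate_hz recording length (s) and sampling rate (Hz,
#'   default 100).
#' @param bleach_coeffs_sig,bleach_coeffs_ref polynomial coefficients
#'   `c(a, b, c)` of `a*t^2 + b*t + c`; must stay strictly positive over
#'   the recording.
#' @param baseline_level home-cage fluorescence baseline (arbitrary units).
#' @param event_times_s,event_amplitudes,event_decay_s calcium transients:
#'   instantaneous rise, single-exponential decay.
#' @param context_step `c(onset_s, offset_s, amplitude)` sustained
#'   elevation, or `NULL`.
#' @param motion_times_s,motion_amplitudes,motion_decay_s shared artifact
#'   transients (exponential decay, present in both channels).
#' @param shared_motion_gain gain of the artifact in the reference channel
#'   (default 1: common mode, exactly removable by subtraction).
#' @param noise_sd white-noise standard deviation (fluorescence units).
#' @param seed optional integer seed.
#'
#' @return a list with `session` (a [photometry_session()]) and `truth`
#'   (bleach coefficients of each recorded channel inclusive of the
#'   baseline factor, de-trended event amplitudes, relative dF/F event
#'   amplitudes, and the context step).
#' @export
synth_photometry <- function(duration_s, rate_hz = 100,
                             bleach_coeffs_sig = c(0, 0, 1),
                             bleach_coeffs_ref = bleach_coeffs_sig,
                             baseline_level = 1,
                             event_times_s = numeric(0),
                             event_amplitudes = numeric(0),
                             event_decay_s = 1.5,
                             context_step = NULL,
                             motion_times_s = numeric(0),
                             motion_amplitudes = numeric(0),
                             motion_decay_s = 0.2,
                             shared_motion_gain = 1,
                             noise_sd = 0,
                             seed = NULL) {
  assert_that(duration_s > 0, "'duration_s' must be positive")
  assert_that(rate_hz > 0, "'rate_hz' must be positive")
  assert_that(length(event_times_s) == length(event_amplitudes),
              "event times and amplitudes must have equal length")
  assert_that(all(event_times_s >= 0 & event_times_s <= duration_s),
              "event times must lie in [0, duration_s]")
  assert_that(all(motion_times_s >= 0 & motion_times_s <= duration_s),
              "motion times must lie in [0, duration_s]")
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  pb_sig <- polyval2(bleach_coeffs_sig, t)
  pb_ref <- polyval2(bleach_coeffs_ref, t)
  assert_that(all(pb_sig > 0) && all(pb_ref > 0),
              "bleaching polynomials must stay strictly positive")

  events <- exp_transients(t, event_times_s, event_amplitudes, event_decay_s)
  ctx <- numeric(n)
  if (!is.null(context_step)) {
    assert_that(length(context_step) == 3 && context_step[1] < context_step[2],
                "'context_step' must be c(onset, offset, amplitude)")
    ctx[t >= context_step[1] & t < context_step[2]] <- context_step[3]
  }
  motion <- exp_transients(t, motion_times_s, motion_amplitudes, motion_decay_s)

  with_seed(seed, {
    noise_s <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    noise_r <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    signal <- pb_sig * (baseline_level + events + ctx) + motion + noise_s
    reference <- pb_ref * baseline_level + shared_motion_gain * motion + noise_r
    session <- photometry_session(time_s = t, signal = signal,
                                  reference = reference, rate_hz = rate_hz)
    truth <- list(
      bleach_coeffs_signal = bleach_coeffs_sig * baseline_level,
      bleach_coeffs_reference = bleach_coeffs_ref * baseline_level,
      event_times_s = event_times_s,
      event_amp_delta_f = event_amplitudes * polyval2(bleach_coeffs_sig,
                                                      event_times_s),
      event_amp_dff = event_amplitudes / baseline_level,
      context_step = context_step)
    list(session = session, truth = truth)
  })
}

polyval2 <- function(coeffs, t) coeffs[1] * t^2 + coeffs[2] * t + coeffs[3]

exp_transients <- function(t, times, amps, decay_s) {
  out <- numeric(length(t))
  for (k in seq_along(times)) {
    sel <- t >= times[k]
    out[sel] <- out[sel] + amps[k] * exp(-(t[sel] - times[k]) / decay_s)
  }
  out
}

#' Synthetic per-cell activity table with known subpopulation structure
#'
#' Emulates the per-cell integrated dF/F tables measured across epochs and
#' days: cells belong to Weak / Intermediate / Strong anticipatory pools
#' (defined by their Pre-epoch activity), respond to the foot shock with a
#' pool-dependent mean, and update their Post activity under a known
#' ground-truth rule.  Under the aversive rule the Post activity of a cell
#' is its Pre activity plus `k_recruit` times its shock response, weighted
#' by pool (`recruit_weights`, Weak recruited fully, Strong not at all).
#' Under the appetitive rule the Post activity is the Pre activity scaled
#' down by a pool-dependent factor `s_scale` (Strong cells drop the most).
#'
#' @param n_cells number of cells (>= 3).
#' @param group_fractions Weak/Intermediate/Strong proportions, summing
#'   to 1.
#' @param pre_means,pre_sds Pre-epoch idF/F mean and sd per pool
#'   (ascending: Weak, Intermediate, Strong).
#' @param fs_means,fs_sds shock-response idF/F per pool (Weak cells respond
#'   most, mirroring the recorded pool contrast).
#' @param rule `"aversive"`, `"appetitive"` or `"none"` (Post = Pre plus
#'   noise).
#' @param k_recruit aversive recruitment gain on the shock response.
#' @param recruit_weights per-pool multiplier on the recruitment term.
#' @param s_scale appetitive per-pool down-scaling fractions.
#' @param post_noise_sd idF/F noise added to each Post day.
#' @param n_days number of Post days (Post activity is redrawn around the
#'   same cell-level target each day, so days are correlated).
#' @param seed optional integer seed.
#'
#' @return list with `table` (long data.frame: `cell_id`, `day`, `epoch`,
#'   `idff`), `labels` (true pool per cell) and `truth` (per-cell Pre, FS
#'   response and noise-free Post target).
#' @export
synth_cell_table <- function(n_cells = 100,
                             group_fractions = c(0.4, 0.4, 0.2),
                             pre_means = c(2, 8, 18),
                             pre_sds = c(0.8, 1.5, 2.5),
                             fs_means = c(40, 28, 18),
                             fs_sds = c(6, 5, 4),
                             rule = c("aversive", "appetitive", "none"),
                             k_recruit = 0.4,
                             recruit_weights = c(1, 0.5, 0),
                             s_scale = c(0.05, 0.3, 0.6),
                             post_noise_sd = 1,
                             n_days = 1,
                             seed = NULL) {
  rule <- match.arg(rule)
  assert_that(n_cells >= 3, "'n_cells' must be at least 3")
  assert_that(abs(sum(group_fractions) - 1) <= 1e-9,
              "'group_fractions' must sum to 1")
  assert_that(all(group_fractions >= 0 & group_fractions <= 1),
              "'group_fractions' must lie in [0, 1]")
  assert_that(all(pre_sds >= 0) && all(fs_sds >= 0) && post_noise_sd >= 0,
              "standard deviations must be non-negative")

  pools <- c("Weak", "Intermediate", "Strong")
  counts <- diff(round(cumsum(c(0, group_fractions)) * n_cells))
  labels <- factor(rep(pools, counts), levels = pools)
  g <- as.integer(labels)

  with_seed(seed, {
    pre <- rnorm(n_cells, pre_means[g], pre_sds[g])
    fs <- rnorm(n_cells, fs_means[g], fs_sds[g])
    post_target <- switch(rule,
      aversive = pre + k_recruit * recruit_weights[g] * fs,
      appetitive = pre - s_scale[g] * pre,
      none = pre)
    rows <- list(
      data.frame(cell_id = seq_len(n_cells), day = 1L, epoch = "Pre",
                 idff = pre),
      data.frame(cell_id = seq_len(n_cells), day = 1L, epoch = "FS",
                 idff = fs))
    for (d in seq_len(n_days)) {
      post_d <- post_target +
        if (post_noise_sd > 0) rnorm(n_cells, 0, post_noise_sd) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = seq_len(n_cells), day = d, epoch = "Post",
                   idff = post_d)
    }
    tab <- do.call(rbind, rows)
    list(table = tab, labels = labels,
         truth = list(pre = pre, fs_response = fs,
                      post_target = post_target, rule = rule))
  })
}

#' Synthetic field-of-view image pair with known alignment transform
#'
#' Builds a day-1 maximal-projection image (Gaussian blobs at random
#' centroids plus optional noise) and a binary cell-mask channel, then
#' produces the day-2 pair by applying a known rotation / translation /
#' scale with bilinear interpolation and zero padding.  Used as ground
#' truth for the cross-day registration.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param n_cells number of cells.
#' @param cell_radius_px Gaussian sd of the blob (mask disks use 1.5x
#'   this radius).
#' @param rotation_deg,translation_px,scale the true day-1 to day-2
#'   transform (rotation about the image centre, then scaling, then
#'   translation `c(dx, dy)` in pixels).
#' @param background_noise_sd intensity noise added independently to each
#'   day's raw image.
#' @param seed optional integer seed.
#'
#' @return list with `day1` and `day2` (each `list(raw, mask)` matrices),
#'   `centroids` (day-1, `x`/`y` columns in pixel coordinates) and
#'   `transform` (an [alignment_transform()]).
#' @export
synth_fov_pair <- function(image_shape = c(96, 96), n_cells = 20,
                           cell_radius_px = 2.5,
                           rotation_deg = 0, translation_px = c(0, 0),
                           scale = 1, background_noise_sd = 0,
                           seed = NULL) {
  assert_that(scale > 0.5 && scale < 2, "'scale' must lie in (0.5, 2)")
  H <- image_shape[1]; W <- image_shape[2]
  tr <- alignment_transform(rotation_deg, translation_px, scale)
  margin <- 4 * cell_radius_px + 2

  min_sep <- 4.2 * cell_radius_px       # mask disks stay disjoint
  with_seed(seed, {
    # rejection-sample centroids that stay in frame after the transform
    # and keep a minimum mutual separation
    cx <- runif(400 * n_cells, margin, W - margin)
    cy <- runif(400 * n_cells, margin, H - margin)
    mapped <- apply_transform(cbind(cx, cy), tr, image_shape)
    ok <- mapped[, 1] > margin & mapped[, 1] < W - margin &
      mapped[, 2] > margin & mapped[, 2] < H - margin
    cx <- cx[ok]; cy <- cy[ok]
    keep <- integer(0)
    for (i in seq_along(cx)) {
      if (!length(keep) ||
          min((cx[i] - cx[keep])^2 + (cy[i] - cy[keep])^2) >= min_sep^2)
        keep <- c(keep, i)
      if (length(keep) == n_cells) break
    }
    if (length(keep) < n_cells)
      stop("transform pushes cells out of frame (or the frame is too ",
           "crowded); reduce the transform or the cell count")
    cx <- cx[keep]; cy <- cy[keep]

    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    raw <- matrix(0, H, W); mask <- matrix(0, H, W)
    for (k in seq_len(n_cells)) {
      d2 <- (xs - cx[k])^2 + (ys - cy[k])^2
      raw <- raw + exp(-d2 / (2 * cell_radius_px^2))
      mask[d2 <= (1.5 * cell_radius_px)^2] <- 1
    }
    raw2 <- .warp_affine(raw, tr$rotation_deg, tr$translation_px[1],
                         tr$translation_px[2], tr$scale)
    mask2 <- .warp_affine(mask, tr$rotation_deg, tr$translation_px[1],
                          tr$translation_px[2], tr$scale)
    if (background_noise_sd > 0) {
      raw <- raw + matrix(rnorm(H * W, 0, background_noise_sd), H, W)
      raw2 <- raw2 + matrix(rnorm(H * W, 0, background_noise_sd), H, W)
    }
    list(day1 = list(raw = raw, mask = mask),
         day2 = list(raw = raw2, mask = mask2),
         centroids = cbind(x = cx, y = cy),
         transform = tr)
  })
}

#' Binary freezing-behavior barcode
#'
#' Encodes annotated freezing bouts as a binary time series at a fixed
#' annotation rate.  Freezing is only scored for bouts of at least 3 s of
#' immobility, so shorter bouts are rejected.
#'
#' @param bout_starts_s,bout_ends_s bout boundaries, seconds;
#'   non-overlapping, each at least 3 s long, within `[0, duration_s]`.
#' @param duration_s observation length, seconds.
#' @param rate_hz annotation rate (default 10 Hz).
#' @return data.frame with columns `time_s` and `frozen` (0/1).
#' @export
synth_behavior_barcode <- function(bout_starts_s, bout_ends_s, duration_s,
                                   rate_hz = 10) {
  assert_that(length(bout_starts_s) == length(bout_ends_s),
              "bout starts and ends must have equal length")
  if (length(bout_starts_s)) {
    durs <- bout_ends_s - bout_starts_s
    if (any(durs < 3))
      stop("freezing bouts must last at least 3 s (immobility criterion); ",
           "offending bout(s): ",
           paste(which(durs < 3), collapse = ", "))
    assert_that(all(bout_starts_s >= 0 & bout_ends_s <= duration_s),
                "bouts must lie within [0, duration_s]")
    o <- order(bout_starts_s)
    assert_that(all(utils::head(bout_ends_s[o], -1) <=
                      utils::tail(bout_starts_s[o], -1) + 1e-12),
                "bouts must not overlap")
  }
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  frozen <- integer(length(t))
  for (k in seq_along(bout_starts_s))
    frozen[t >= bout_starts_s[k] & t < bout_ends_s[k]] <- 1L
  data.frame(time_s = t, frozen = frozen)
}
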