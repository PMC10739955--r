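#' Similarity transform between imaging days
#'
#' A rotation about the image centre, followed by isotropic scaling and a
#' pixel translation: the transform family used to register miniscope
#' fields of view across recording days.
#'
#' @param rotation_deg rotation, degrees (counter-clockwise in x/y pixel
#'   coordinates).
#' @param translation_px `c(dx, dy)` pixels.
#' @param scale isotropic scale factor (> 0).
#' @return an object of class `alignment_transform`.
#' @export
alignment_transform <- function(rotation_deg = 0, translation_px = c(0, 0),
                                scale = 1) {
  assert_that(scale > 0, "'scale' must be positive")
  structure(list(rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 scale = scale),
            class = "alignment_transform")
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf("Transform: rotation %.3f deg, translation (%.3f, %.3f) px, scale %.4f\n",
              x$rotation_deg, x$translation_px[1], x$translation_px[2],
              x$scale))
  invisible(x)
}

#' @rdname alignment_transform
#' @param points two-column matrix of `(x, y)` pixel coordinates.
#' @param transform an `alignment_transform`.
#' @param image_shape `c(height, width)`; the rotation/scaling centre is
#'   the image centre.
#' @export
apply_transform <- function(points, transform, image_shape) {
  points <- matrix(as.numeric(points), ncol = 2)
  cx <- (image_shape[2] + 1) / 2; cy <- (image_shape[1] + 1) / 2
  th <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  centered <- sweep(points, 2, c(cx, cy))
  out <- transform$scale * centered %*% t(R)
  sweep(out, 2, c(cx + transform$translation_px[1],
                  cy + transform$translation_px[2]), `+`)
}

#' @rdname alignment_transform
#' @export
invert_transform <- function(transform) {
  th <- -transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  alignment_transform(-transform$rotation_deg,
                      as.numeric(-(R %*% transform$translation_px) /
                                   transform$scale),
                      1 / transform$scale)
}

#' Warp an image by a similarity transform
#'
#' Bilinear interpolation with zero padding; features move the way
#' [apply_transform()] moves points.
#'
#' @param img numeric matrix.
#' @param transform an [alignment_transform()].
#' @return warped matrix of the same shape.
#' @export
warp_image <- function(img, transform) {
  .warp_affine(img, transform$rotation_deg, transform$translation_px[1],
               transform$translation_px[2], transform$scale)
}

#' Integrated dF/F of a single-cell trace
#'
#' The per-cell activity measure: the dF/F trace is bin-averaged at
#' `sample_s` resolution over a window (3 min by default) and the mean is
#' multiplied by 100.
#'
#' @param values dF/F samples.
#' @param time_s sample times, seconds.
#' @param window `c(start, end)` seconds; default `c(0, 180)`.
#' @param sample_s resampling bin, seconds (default 0.1).
#' @return scalar idF/F.
#' @export
integrated_dff <- function(values, time_s, window = c(0, 180),
                           sample_s = 0.1) {
  assert_that(min(time_s) <= window[1] + 1e-9 &&
                max(time_s) >= window[2] - sample_s - 1e-9,
              "trace does not cover the requested window")
  edges <- seq(window[1], window[2], by = sample_s)
  idx <- findInterval(time_s, edges, rightmost.closed = FALSE)
  sel <- idx >= 1 & idx <= length(edges) - 1 & time_s < window[2]
  binmeans <- tapply(values[sel], idx[sel], mean)
  100 * mean(binmeans)
}

#' Global alignment metric across recording days
#'
#' Sum of Frobenius distances between day images: over all unordered day
#' pairs (default, matching the all-pairs objective) or between each day
#' and a fixed reference day.
#'
#' @param images list of equally shaped numeric matrices, one per day.
#' @param reference `NULL` for all unordered pairs, or the index of the
#'   reference day.
#' @return scalar GA value.
#' @export
global_alignment_metric <- function(images, reference = NULL) {
  n <- length(images)
  assert_that(n >= 2, "need at least two days")
  ga <- 0
  if (is.null(reference)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      ga <- ga + .frob_dist(images[[i]], images[[j]])
  } else {
    for (i in setdiff(seq_len(n), reference))
      ga <- ga + .frob_dist(images[[i]], images[[reference]])
  }
  ga
}

#' Weighted two-channel alignment criterion
#'
#' Linear combination of the mask-channel and raw-channel global
#' alignment metrics with weights 0.3 (cell masks) and 0.7 (raw image).
#'
#' @param ga_mask,ga_raw channel metrics.
#' @param weights `c(mask, raw)` weights.
#' @return scalar.
#' @export
weighted_metric <- function(ga_mask, ga_raw, weights = c(0.3, 0.7)) {
  assert_that(is.finite(ga_mask) && is.finite(ga_raw),
              "metrics must be finite")
  weights[1] * ga_mask + weights[2] * ga_raw
}

#' Cross-day field-of-view registration by stochastic descent
#'
#' Aligns the maximal-projection (raw) and cell-mask channels of several
#' recording days by randomly perturbing each day's rotation / translation
#' / scale and keeping a perturbation only if the weighted alignment
#' criterion (`0.3 * GA_mask + 0.7 * GA_raw`) decreases.  The perturbation
#' size is halved every `halve_every` iterations and the day being
#' perturbed cycles every `swap_every` iterations.  Several restarts from
#' different initial transforms are run and the best final criterion wins.
#'
#' @param days list of days, each `list(raw = matrix, mask = matrix)`.
#' @param reference index of the day held fixed (default 1).
#' @param iterations total iterations per restart (default 10000).
#' @param restarts number of random restarts (default 5; the first starts
#'   from the identity).
#' @param seed optional integer seed.
#' @param init_step initial perturbation scales
#'   `c(rot_deg, trans_px, scale)`.
#' @param init_range initial-condition ranges for restarts beyond the
#'   first, same layout as `init_step`.
#' @param halve_every,swap_every schedule constants.
#' @param weights `c(mask, raw)` channel weights.
#' @param pairwise `TRUE` for the all-unordered-pairs metric, `FALSE` for
#'   distance to the reference day only.
#' @param normalize intensity-normalize each channel to `[0, 1]` per day
#'   before computing metrics (keeps raw and mask magnitudes
#'   commensurate).
#'
#' @return an object of class `fov_alignment`: per-day
#'   [alignment_transform()]s (reference day = identity), the final
#'   criterion `metric`, per-channel GA values, the accepted-metric
#'   `trajectory` of the winning restart, and `restart_metrics`.
#' @export
stochastic_align <- function(days, reference = 1, iterations = 10000,
                             restarts = 5, seed = NULL,
                             init_step = c(5, 10, 0.1),
                             init_range = c(5, 10, 0.05),
                             halve_every = 500, swap_every = 400,
                             weights = c(0.3, 0.7), pairwise = TRUE,
                             normalize = TRUE) {
  nd <- length(days)
  assert_that(nd >= 2, "need at least two days")
  shp <- dim(days[[1]]$raw)
  for (d in days)
    assert_that(all(dim(d$raw) == shp) && all(dim(d$mask) == shp),
                "all day images must share one shape")
  norm01 <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  raws <- lapply(days, function(d) if (normalize) norm01(d$raw) else d$raw)
  masks <- lapply(days, function(d) if (normalize) norm01(d$mask) else d$mask)
  movable <- setdiff(seq_len(nd), reference)
  refpt <- if (pairwise) NULL else reference

  run_restart <- function(tr0) {
    tr <- tr0
    w_raw <- raws; w_mask <- masks
    for (k in movable) {
      w_raw[[k]] <- warp_image(raws[[k]], tr[[k]])
      w_mask[[k]] <- warp_image(masks[[k]], tr[[k]])
    }
    cur <- weighted_metric(global_alignment_metric(w_mask, refpt),
                           global_alignment_metric(w_raw, refpt), weights)
    traj <- numeric(iterations)
    step <- init_step
    for (it in seq_len(iterations)) {
      sc <- step / 2^((it - 1) %/% halve_every)
      day <- movable[((it - 1) %/% swap_every) %% length(movable) + 1]
      cand <- tr[[day]]
      cand$rotation_deg <- cand$rotation_deg + runif(1, -sc[1], sc[1])
      cand$translation_px <- cand$translation_px + runif(2, -sc[2], sc[2])
      cand$scale <- max(0.1, cand$scale + runif(1, -sc[3], sc[3]))
      cr <- warp_image(raws[[day]], cand)
      cm <- warp_image(masks[[day]], cand)
      tr_raw <- w_raw; tr_mask <- w_mask
      tr_raw[[day]] <- cr; tr_mask[[day]] <- cm
      m <- weighted_metric(global_alignment_metric(tr_mask, refpt),
                           global_alignment_metric(tr_raw, refpt), weights)
      if (m < cur) {          # strict decrease; ties do not move
        cur <- m; tr[[day]] <- cand
        w_raw <- tr_raw; w_mask <- tr_mask
      }
      traj[it] <- cur
    }
    list(transforms = tr, metric = cur, trajectory = traj,
         ga_mask = global_alignment_metric(w_mask, refpt),
         ga_raw = global_alignment_metric(w_raw, refpt))
  }

  with_seed(seed, {
    best <- NULL
    restart_metrics <- numeric(restarts)
    for (r in seq_len(restarts)) {
      tr0 <- replicate(nd, alignment_transform(), simplify = FALSE)
      if (r > 1) {
        for (k in movable)
          tr0[[k]] <- alignment_transform(
            runif(1, -init_range[1], init_range[1]),
            runif(2, -init_range[2], init_range[2]),
            1 + runif(1, -init_range[3], init_range[3]))
      }
      res <- run_restart(tr0)
      restart_metrics[r] <- res$metric
      if (is.null(best) || res$metric < best$metric) best <- res
    }
    structure(c(best, list(restart_metrics = restart_metrics,
                           reference = reference)),
              class = "fov_alignment")
  })
}

#' @export
print.fov_alignment <- function(x, ...) {
  cat("Cross-day FOV alignment\n")
  cat(sprintf("  final criterion %.4f (mask GA %.4f, raw GA %.4f)\n",
              x$metric, x$ga_mask, x$ga_raw))
  for (k in seq_along(x$transforms)) {
    cat(sprintf("  day %d%s: ", k,
                if (k == x$reference) " (reference)" else ""))
    print(x$transforms[[k]])
  }
  invisible(x)
}

#' Centroids of labeled or binary cell masks
#'
#' Connected components (4-connectivity) of a binary mask, or the unique
#' positive labels of a labeled mask, reduced to their centroids.
#'
#' @param mask numeric matrix; zero is background.
#' @return two-column matrix of `(x, y)` centroids (pixel coordinates).
#' @export
mask_centroids <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  labs <- unique(mask[mask > 0])
  if (length(labs) > 1 && all(abs(labs - round(labs)) < 1e-9)) {
    # integer-labeled mask: one centroid per label
    out <- t(vapply(sort(labs), function(l) {
      idx <- which(mask == l)
      c(mean((idx - 1) %/% H + 1), mean((idx - 1) %% H + 1))
    }, numeric(2)))
    colnames(out) <- c("x", "y")
    return(out)
  }
  # continuous (e.g. resampled) masks: binarize at half maximum
  if (length(labs) > 1) mask <- (mask >= 0.5 * max(mask)) + 0
  seen <- matrix(FALSE, H, W)
  cents <- list()
  for (start in which(mask > 0)) {
    r0 <- (start - 1) %% H + 1; c0 <- (start - 1) %/% H + 1
    if (seen[r0, c0]) next
    queue <- start; seen[r0, c0] <- TRUE
    px <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      px <- c(px, cur)
      r <- (cur - 1) %% H + 1; cc <- (cur - 1) %/% H + 1
      for (nb in list(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))) {
        if (nb[1] >= 1 && nb[1] <= H && nb[2] >= 1 && nb[2] <= W &&
            !seen[nb[1], nb[2]] && mask[nb[1], nb[2]] > 0) {
          seen[nb[1], nb[2]] <- TRUE
          queue <- c(queue, (nb[2] - 1) * H + nb[1])
        }
      }
    }
    r <- (px - 1) %% H + 1; cc <- (px - 1) %/% H + 1
    cents[[length(cents) + 1]] <- c(mean(cc), mean(r))
  }
  out <- do.call(rbind, cents)
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  colnames(out) <- c("x", "y")
  out
}

#' Cross-day cell correspondence by greedy nearest-centroid matching
#'
#' Matches cells of an aligned day to reference cells one-to-one: the
#' globally closest centroid pair is matched first, then removed, until no
#' pair under the distance cap remains.  Unmatched cells are flagged.
#'
#' @param centroids_ref,centroids_day two-column `(x, y)` matrices in the
#'   common (reference) frame.
#' @param max_dist_px matching cap, pixels (default 6).
#' @return list with `matches` (data.frame `cell_id_day`, `cell_id_ref`,
#'   `distance_px`), `unmatched_day`, `unmatched_ref` (integer indices).
#' @export
match_cells <- function(centroids_ref, centroids_day, max_dist_px = 6) {
  nr <- nrow(centroids_ref); nd <- nrow(centroids_day)
  if (nr == 0 || nd == 0)
    return(list(matches = data.frame(cell_id_day = integer(0),
                                     cell_id_ref = integer(0),
                                     distance_px = numeric(0)),
                unmatched_day = seq_len(nd), unmatched_ref = seq_len(nr)))
  D <- sqrt(outer(centroids_day[, 1], centroids_ref[, 1], `-`)^2 +
              outer(centroids_day[, 2], centroids_ref[, 2], `-`)^2)
  matches <- list()
  repeat {
    m <- which.min(D)
    if (!length(m) || D[m] > max_dist_px || !is.finite(D[m])) break
    i <- (m - 1) %% nd + 1; j <- (m - 1) %/% nd + 1
    matches[[length(matches) + 1]] <-
      data.frame(cell_id_day = i, cell_id_ref = j, distance_px = D[m])
    D[i, ] <- Inf; D[, j] <- Inf
  }
  mdf <- if (length(matches)) do.call(rbind, matches) else
    data.frame(cell_id_day = integer(0), cell_id_ref = integer(0),
               distance_px = numeric(0))
  list(matches = mdf,
       unmatched_day = setdiff(seq_len(nd), mdf$cell_id_day),
       unmatched_ref = setdiff(seq_len(nr), mdf$cell_id_ref))
}

#' Read and write two-channel FOV images as multi-page TIFF
#'
#' Page 1 holds the raw maximal-projection image (intensity-normalized to
#' `[0, 1]` on write), page 2 the cell-mask channel.
#'
#' @param fov `list(raw, mask)` matrices.
#' @param path file path.
#' @return `read_fov_tiff()` returns `list(raw, mask)`.
#' @export
write_fov_tiff <- function(fov, path) {
  norm01 <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  tiff::writeTIFF(list(norm01(fov$raw), norm01(fov$mask)), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_fov_tiff
#' @export
read_fov_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  assert_that(length(pages) >= 2, "expected a two-page TIFF (raw, mask)")
  list(raw = pages[[1]], mask = pages[[2]])
}
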