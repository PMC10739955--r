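#' Cross-day population activity matrix
#'
#' Stacks per-cell activity traces recorded on several days into one
#' cells x time matrix: rows are reference cell identities, columns the
#' concatenated, time-ordered samples of each day.  Cells lacking a
#' correspondence on any included day are dropped (with a message).
#'
#' @param traces_by_day list of days; each day is a cells x samples
#'   matrix in that day's own cell order.
#' @param correspondence list of integer vectors, one per day, mapping
#'   each day's rows to reference cell ids (`NA` = unmatched).  The first
#'   day may be `NULL` meaning identity.
#' @param day_labels optional labels for the column annotation.
#' @return an object of class `population_matrix`: list with `X`,
#'   `cell_ids` and `columns` (data.frame `day`, `sample`).
#' @export
build_matrix <- function(traces_by_day, correspondence = NULL,
                         day_labels = seq_along(traces_by_day)) {
  nd <- length(traces_by_day)
  assert_that(nd >= 1, "need at least one day")
  if (is.null(correspondence))
    correspondence <- vector("list", nd)
  refids <- lapply(seq_len(nd), function(d) {
    ids <- correspondence[[d]]
    if (is.null(ids)) seq_len(nrow(traces_by_day[[d]])) else ids
  })
  common <- Reduce(intersect, lapply(refids, function(x) x[!is.na(x)]))
  if (!length(common)) stop("no cells are matched across all days")
  common <- sort(common)
  dropped <- length(unique(unlist(refids))) - length(common)
  if (dropped > 0)
    message(dropped, " cell(s) unmatched on some day; dropped")
  blocks <- lapply(seq_len(nd), function(d) {
    rows <- match(common, refids[[d]])
    traces_by_day[[d]][rows, , drop = FALSE]
  })
  X <- do.call(cbind, blocks)
  cols <- do.call(rbind, lapply(seq_len(nd), function(d)
    data.frame(day = day_labels[d], sample = seq_len(ncol(blocks[[d]])))))
  structure(list(X = X, cell_ids = common, columns = cols),
            class = "population_matrix")
}

#' Principal component analysis via singular value decomposition
#'
#' Applies the SVD to the (optionally column-centered) population matrix.
#' Variance fractions are the normalized squared singular values;
#' projections of each time sample onto the components serve the
#' state-space plots.
#'
#' @param X cells x time matrix (or a `population_matrix`).
#' @param center center each column (time sample) across cells before
#'   decomposing (default TRUE).
#' @return list with `components` (cells x k loadings), `projections`
#'   (time x k), `singular_values`, `variance_fraction`.
#' @export
pca_svd <- function(X, center = TRUE) {
  if (inherits(X, "population_matrix")) X <- X$X
  X <- as.matrix(X)
  assert_that(nrow(X) >= 2 && ncol(X) >= 2,
              "need at least a 2 x 2 matrix")
  Xc <- if (center) sweep(X, 2, colMeans(X)) else X
  if (all(abs(Xc) < .Machine$double.eps * 100))
    stop("matrix is degenerate (all entries equal after centering)")
  sv <- svd(Xc)
  vf <- sv$d^2 / sum(sv$d^2)
  list(components = sv$u, projections = sweep(sv$v, 2, sv$d, `*`),
       singular_values = sv$d, variance_fraction = vf)
}

#' Paired Pre/Post comparison
#'
#' Two-tailed paired t-test plus effect summary for per-cell (or
#' per-animal) epoch means.
#'
#' @param pre_values,post_values equal-length paired measurements.
#' @return list with `mean_diff`, `t`, `df`, `p` and `conf_int` (95%).
#' @export
paired_comparison <- function(pre_values, post_values) {
  assert_that(length(pre_values) == length(post_values),
              "paired vectors must have equal length")
  assert_that(length(pre_values) >= 2, "need at least 2 pairs")
  d <- post_values - pre_values
  if (sd(d) == 0) {
    if (mean(d) == 0)                 # identical vectors: no effect
      return(list(mean_diff = 0, t = 0, df = length(d) - 1, p = 1,
                  conf_int = c(0, 0)))
    warning("zero variance of paired differences; t is infinite")
    return(list(mean_diff = mean(d), t = Inf * sign(mean(d)),
                df = length(d) - 1, p = 0,
                conf_int = c(mean(d), mean(d))))
  }
  tt <- t.test(post_values, pre_values, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       conf_int = as.numeric(tt$conf.int))
}

#' Correlation of per-cell activity between two epochs
#'
#' Pearson correlation with the regression-slope test used for the
#' Pre-vs-Post scatter analyses.
#'
#' @param pre_values,post_values per-cell values (>= 3 pairs).
#' @return list with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
pre_post_correlation <- function(pre_values, post_values) {
  assert_that(length(pre_values) == length(post_values),
              "vectors must have equal length")
  assert_that(length(pre_values) >= 3, "need at least 3 pairs")
  if (sd(pre_values) == 0 || sd(post_values) == 0)
    stop("zero variance in one of the epochs; correlation undefined")
  ct <- cor.test(pre_values, post_values)
  fit <- lm(post_values ~ pre_values)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(pre_values))
}

#' Does the shock response predict recruitment?
#'
#' Within each subpopulation, correlates the foot-shock-epoch response
#' with the activity change from Pre to Post.  In the recorded data this
#' correlation is strong for Weak cells and absent for Strong cells.
#'
#' @param fs_response per-cell shock-epoch activity.
#' @param post_minus_pre per-cell activity change.
#' @param labels factor of pool labels (same length).
#' @return data.frame with one row per group: `label`, `n`, `r`, `slope`,
#'   `p`.  Groups with fewer than 3 cells are skipped with a warning.
#' @export
recruitment_regression <- function(fs_response, post_minus_pre, labels) {
  assert_that(length(fs_response) == length(post_minus_pre) &&
                length(labels) == length(fs_response),
              "inputs must have equal length")
  out <- list()
  for (g in levels(factor(labels))) {
    sel <- labels == g
    if (sum(sel) < 3) {
      warning("group '", g, "' has fewer than 3 cells; skipped")
      next
    }
    if (sd(fs_response[sel]) == 0)
      stop("zero variance of the shock response in group '", g, "'")
    pc <- pre_post_correlation(fs_response[sel], post_minus_pre[sel])
    out[[g]] <- data.frame(label = g, n = sum(sel), r = pc$r,
                           slope = pc$slope, p = pc$p)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Total freezing time in an observation window
#'
#' Sums freezing-bout durations inside the window from a binary behavior
#' barcode; bouts shorter than the 3 s immobility criterion are excluded.
#'
#' @param barcode data.frame with `time_s` and `frozen` columns (see
#'   [synth_behavior_barcode()]).
#' @param window `c(start, end)` seconds; default the first 3 minutes.
#' @return list with `seconds` frozen and `fraction` of the window.
#' @export
freezing_time <- function(barcode, window = c(0, 180)) {
  sel <- barcode$time_s >= window[1] & barcode$time_s < window[2]
  assert_that(any(sel), "barcode does not cover the window")
  x <- barcode$frozen[sel]
  dt <- if (sum(sel) > 1) diff(barcode$time_s[sel][1:2]) else 1
  r <- rle(x)
  ends <- cumsum(r$lengths)
  total <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1) {
      dur <- r$lengths[k] * dt
      if (dur >= 3) total <- total + dur
    }
  }
  list(seconds = total, fraction = total / (diff(window)))
}

#' Pre/Post recall statistics by subpopulation
#'
#' Convenience wrapper reproducing the recall analysis chain on a
#' long-format cell activity table: per-pool paired Pre/Post comparisons,
#' the overall Pre-Post correlation, the Weak-vs-Strong comparison at
#' Post, and the per-pool recruitment regression on the shock response.
#'
#' @param table long data.frame with `cell_id`, `day`, `epoch`, `idff`
#'   (as produced by [synth_cell_table()]).
#' @param clusters a [cluster_cells()] assignment (rows in `cell_id`
#'   order); `NULL` clusters on Pre activity with the default method.
#' @param day which Post day to analyse (default 1).
#' @return list with `per_group` (paired stats per pool), `correlation`,
#'   `post_group_test` (Weak vs Strong at Post, two-sample t),
#'   `recruitment` (if an FS epoch is present) and the extracted
#'   per-cell `pre`, `post`, `fs` vectors with `labels`.
#' @export
recall_stats <- function(table, clusters = NULL, day = 1) {
  need <- c("cell_id", "day", "epoch", "idff")
  assert_that(all(need %in% names(table)),
              "table must have cell_id, day, epoch, idff columns")
  wide <- function(ep, d) {
    rows <- table[table$epoch == ep & table$day == d, ]
    rows$idff[order(rows$cell_id)]
  }
  pre <- wide("Pre", 1)
  post <- wide("Post", day)
  assert_that(length(pre) == length(post) && length(pre) > 0,
              "Pre and Post epochs must cover the same cells")
  fs <- if (any(table$epoch == "FS")) wide("FS", 1) else NULL
  if (is.null(clusters)) clusters <- cluster_cells(pre)
  labels <- clusters$label
  per_group <- lapply(split(seq_along(pre), labels), function(i)
    if (length(i) >= 2) paired_comparison(pre[i], post[i]) else NULL)
  pg <- labels == "Weak" | labels == "Strong"
  post_group_test <- if (sum(labels == "Weak") >= 2 &&
                           sum(labels == "Strong") >= 2)
    t.test(post[labels == "Weak"], post[labels == "Strong"]) else NULL
  list(per_group = per_group,
       correlation = pre_post_correlation(pre, post),
       post_group_test = post_group_test,
       recruitment = if (!is.null(fs))
         recruitment_regression(fs, post - pre, labels) else NULL,
       pre = pre, post = post, fs = fs, labels = labels)
}
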