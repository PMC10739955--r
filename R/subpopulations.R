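#' Affinity propagation clustering
#'
#' Frey–Dueck message passing on a similarity matrix.  Similarity is the
#' negative squared Euclidean distance; the shared preference (the
#' self-similarity controlling the number of exemplars) defaults to the
#' minimum off-diagonal similarity, the `q = 0` convention that favors a
#' small number of clusters.
#'
#' @param features numeric vector or matrix (rows = cells).
#' @param preference shared preference; `NULL` uses the minimum input
#'   similarity, `"median"` the median (more clusters).
#' @param damping message damping factor in `[0.5, 1)`.
#' @param max_iter maximum iterations.
#' @param conv_iter stop once the exemplar set is unchanged this many
#'   consecutive iterations.
#' @return list with `exemplars` (indices), `assignment` (exemplar index
#'   per cell), `clusters` (list of member indices per exemplar) and
#'   `iterations`.
#' @export
affinity_propagation <- function(features, preference = NULL,
                                 damping = 0.9, max_iter = 1000,
                                 conv_iter = 50) {
  X <- as.matrix(features)
  n <- nrow(X)
  assert_that(n >= 3, "need at least 3 cells")
  assert_that(all(is.finite(X)), "features must be finite")
  D2 <- as.matrix(stats::dist(X))^2
  S <- -D2
  off <- S[row(S) != col(S)]
  pref <- if (is.null(preference)) min(off)
  else if (identical(preference, "median")) median(off)
  else preference
  diag(S) <- pref

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  ex_prev <- integer(0); stable <- 0L; it_used <- max_iter
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    idx_max <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), idx_max)]
    AS2 <- AS; AS2[cbind(seq_len(n), idx_max)] <- -Inf
    m2 <- apply(AS2, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), idx_max)] <- S[cbind(seq_len(n), idx_max)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    tmp <- pmax(R, 0); diag(tmp) <- diag(R)
    pre <- matrix(colSums(tmp), n, n, byrow = TRUE) - tmp
    dA <- diag(pre)
    Anew <- pmin(pre, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter) { it_used <- it; break }
    } else stable <- 0L
    ex_prev <- ex
    if (it == max_iter && length(ex) && stable < conv_iter)
      stop("affinity propagation did not converge within ", max_iter,
           " iterations")
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) {
    # degenerate (e.g. all points identical): a single net-similarity exemplar
    ex <- which.max(colSums(S))
  }
  assignment <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assignment[ex] <- ex
  clusters <- split(seq_len(n), assignment)
  list(exemplars = sort(unique(assignment)), assignment = assignment,
       clusters = clusters, iterations = it_used, similarity = S)
}

#' Exemplar-based agglomerative merging of affinity-propagation clusters
#'
#' Iteratively merges the pair of clusters whose best joint exemplar (the
#' member maximizing the mean similarity of the merged cluster to it)
#' yields the highest within-cluster similarity, until `k` clusters
#' remain.
#'
#' @param ap result of [affinity_propagation()].
#' @param k target number of clusters (default 3).
#' @return list with `clusters` (list of member index vectors),
#'   `exemplars` and `assignment` (cluster number per cell).
#' @export
agglomerate_exemplars <- function(ap, k = 3) {
  clusters <- unname(ap$clusters)
  exemplars <- as.integer(names(ap$clusters))
  S <- ap$similarity
  if (length(clusters) < k)
    stop("affinity propagation found ", length(clusters),
         " clusters; cannot agglomerate to k = ", k,
         " (try a lower k)")
  best_joint <- function(members) {
    scores <- colMeans(S[members, members, drop = FALSE])
    list(ex = members[which.max(scores)], score = max(scores))
  }
  while (length(clusters) > k) {
    nc <- length(clusters)
    best <- NULL
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      bj <- best_joint(c(clusters[[i]], clusters[[j]]))
      if (is.null(best) || bj$score > best$score)
        best <- c(bj, list(i = i, j = j))
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$i]] <- merged
    exemplars[best$i] <- best$ex
    clusters[[best$j]] <- NULL
    exemplars <- exemplars[-best$j]
  }
  n <- length(ap$assignment)
  assignment <- integer(n)
  for (c in seq_along(clusters)) assignment[clusters[[c]]] <- c
  list(clusters = clusters, exemplars = exemplars, assignment = assignment)
}

#' Data-driven Weak / Intermediate / Strong subpopulations
#'
#' Partitions cells into anticipatory pools from a single activity
#' feature (by convention the Pre-epoch idF/F).  Two classifiers are
#' provided: affinity propagation followed by exemplar-based
#' agglomerative merging to `k` clusters (`"ap_agg"`, the data-driven
#' default), and a mean +/- `k_sd` standard-deviation rule (`"sd"`).
#' Clusters are labeled Weak, Intermediate, Strong in ascending order of
#' their mean feature value.
#'
#' @param values per-cell feature (e.g. Pre idF/F).
#' @param method `"ap_agg"` or `"sd"`.
#' @param k number of pools for `"ap_agg"` (default 3).
#' @param k_sd sd multiplier for `"sd"` (default 1).
#' @param ... passed to [affinity_propagation()].
#' @return an object of class `cell_clusters`: data.frame with `cell_id`,
#'   `label` (ordered factor), `exemplar` (for `ap_agg`), plus attributes
#'   `method` and `k`.
#' @export
cluster_cells <- function(values, method = c("ap_agg", "sd"), k = 3,
                          k_sd = 1, ...) {
  method <- match.arg(method)
  n <- length(values)
  if (method == "ap_agg") {
    ap <- affinity_propagation(values, ...)
    agg <- if (length(ap$clusters) > k) agglomerate_exemplars(ap, k) else {
      if (length(ap$clusters) < k)
        stop("affinity propagation found ", length(ap$clusters),
             " clusters; cannot form k = ", k, " pools (try a lower k)")
      list(clusters = unname(ap$clusters),
           exemplars = as.integer(names(ap$clusters)),
           assignment = match(ap$assignment, sort(unique(ap$assignment))))
    }
    means <- vapply(agg$clusters, function(m) mean(values[m]), numeric(1))
    ord <- order(means)
    lev <- if (k == 3) c("Weak", "Intermediate", "Strong") else
      paste0("pool_", seq_len(k))
    lab <- factor(lev[match(agg$assignment, ord)], levels = lev,
                  ordered = TRUE)
    exemplar <- agg$exemplars[agg$assignment]
    df <- data.frame(cell_id = seq_len(n), label = lab, exemplar = exemplar)
  } else {
    assert_that(n >= 2, "need at least 2 values")
    mu <- mean(values); s <- sd(values)
    lev <- c("Weak", "Intermediate", "Strong")
    if (s == 0) {
      warning("zero variance: all cells classified Intermediate")
      lab <- factor(rep("Intermediate", n), levels = lev, ordered = TRUE)
    } else {
      lab <- factor(ifelse(values < mu - k_sd * s, "Weak",
                    ifelse(values > mu + k_sd * s, "Strong",
                           "Intermediate")),
                    levels = lev, ordered = TRUE)
    }
    df <- data.frame(cell_id = seq_len(n), label = lab, exemplar = NA_integer_)
  }
  structure(df, method = method, k = k, class = c("cell_clusters",
                                                  "data.frame"))
}

#' @export
print.cell_clusters <- function(x, ...) {
  cat("Cell subpopulations (", attr(x, "method"), ")\n", sep = "")
  print(table(x$label))
  invisible(x)
}
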