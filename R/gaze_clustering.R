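#' Extract the time-by-subject gaze matrix for a window
#'
#' Resamples every subject's x-gaze onto a common grid at the nominal
#' sampling rate inside `[start, end)`. Invalid samples are linearly
#' interpolated from valid neighbours; a subject with more than half of the
#' window invalid is excluded with a warning.
#'
#' @param gaze Long gaze data.frame (`subject`, `t_s`, `x`, `valid`) for one
#'   session.
#' @param start_s,end_s Window bounds in seconds.
#' @param sample_rate_hz Grid rate (default 60).
#' @param max_invalid Exclusion threshold on the invalid fraction
#'   (default 0.5).
#' @return A numeric matrix, rows = grid time samples, columns = subjects,
#'   with attributes `t_s` (row timestamps) and `window`.
#' @export
extract_window_matrix <- function(gaze, start_s, end_s, sample_rate_hz = 60,
                                  max_invalid = 0.5) {
  stopifnot(end_s > start_s)
  n <- as.integer(round((end_s - start_s) * sample_rate_hz))
  grid <- start_s + (seq_len(n) - 1L) / sample_rate_hz
  subjects <- sort(unique(as.character(gaze$subject)))
  cols <- list()
  for (s in subjects) {
    g <- gaze[gaze$subject == s & gaze$t_s >= start_s - 0.5 / sample_rate_hz &
                gaze$t_s < end_s, ]
    if (nrow(g) == 0) {
      warning("subject ", s, " has no samples in window; excluded")
      next
    }
    valid <- if ("valid" %in% names(g)) as.logical(g$valid) else
      rep(TRUE, nrow(g))
    if (mean(!valid) > max_invalid) {
      warning("subject ", s, " has >", round(100 * max_invalid),
              "% invalid samples in window; excluded")
      next
    }
    x <- approx(g$t_s[valid], g$x[valid], xout = grid, rule = 2)$y
    cols[[s]] <- x
  }
  if (length(cols) == 0) stop("no subject covers the window", call. = FALSE)
  m <- do.call(cbind, cols)
  attr(m, "t_s") <- grid
  attr(m, "window") <- c(start_s = start_s, end_s = end_s)
  m
}

#' Gaze coefficient of variation
#'
#' Sample standard deviation of the x-gaze divided by its mean over a
#' continuous segment, the scale-free measure of temporal gaze dispersion.
#'
#' @param x Numeric vector of x-gaze samples (a continuous segment), or a
#'   gaze data.frame with columns `t_s`, `x` and optionally `valid`.
#' @param start_s,end_s Optional window bounds applied when `x` is a
#'   data.frame.
#' @return The coefficient of variation (dimensionless).
#' @export
#' @examples
#' gaze_cv(c(0.4, 0.6, 0.4, 0.6))
gaze_cv <- function(x, start_s = NULL, end_s = NULL) {
  if (is.data.frame(x)) {
    g <- x
    if (!is.null(start_s)) g <- g[g$t_s >= start_s & g$t_s < end_s, ]
    if ("valid" %in% names(g)) g <- g[as.logical(g$valid), ]
    x <- g$x
  }
  if (length(x) < 2) stop("need at least 2 valid samples", call. = FALSE)
  m <- mean(x)
  if (abs(m) <= 1e-12) stop("mean gaze position is ~0; CV undefined",
                            call. = FALSE)
  sd(x) / m
}

#' Ward agglomerative clustering of time samples
#'
#' Clusters the rows (time samples) of a time-by-subject gaze matrix by
#' Ward's minimum-variance criterion on Euclidean distances, yielding "time
#' clusters" of the window. When `k` is not given it is chosen as the number
#' of clusters whose cut corresponds to the largest gap between successive
#' merge heights, restricted to `k_range` (2-5 by default, where 3 is the
#' typical outcome for windows spanning about three core rest positions).
#'
#' The gap is taken on the ratio of successive merge heights (Ward heights
#' grow with cluster size, so absolute gaps are biased toward small k).
#' Because Ward isolates transient gaze excursions (one exploratory
#' glance, a saccade in flight) in its very top merges — which would mask
#' the sustained regime structure from any truncation rule — automatic
#' selection first despikes the window: samples deviating from their
#' subject's 1-s running median by more than `spike_mads` robust standard
#' deviations are set aside, the tree is rebuilt and truncated on the
#' remaining rows, and the spike rows are reattached to the nearest
#' cluster centroid. Reattached rows sit far from their cluster mean, so
#' they never become central objects. An explicit `k` bypasses all of
#' this and cuts the tree directly.
#'
#' @param m Matrix from [extract_window_matrix()] (rows = time samples).
#' @param k Number of clusters; NULL for automatic selection.
#' @param k_range Candidate k values for automatic selection.
#' @param spike_mads Despiking threshold in median-absolute-deviation
#'   units of the running-median residual (default 6; a floor of 0.05
#'   normalized units guards near-constant windows).
#' @return An object of class `cluster_result`: list with `assignments`
#'   (integer per row), `k`, `within_class_pct`, `between_class_pct`,
#'   `dissimilarity`, `central_objects` (see [central_objects()]),
#'   `time_centroids`, `heights` (Ward merge heights of the full matrix)
#'   and `hclust`.
#' @export
ward_cluster <- function(m, k = NULL, k_range = 2:5, spike_mads = 6) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (!is.null(k)) {
    stop_if_not_number(k, "k", lower = 1)
    if (k > n) stop("k exceeds the number of time samples", call. = FALSE)
  }
  hc <- hclust(dist(m), method = "ward.D2")
  h <- hc$height  # non-decreasing by construction
  gap_rule <- function(hh, nn, kr) {
    cand <- intersect(kr, 2:max(nn - 1, 2))
    gaps <- vapply(cand, function(kk) {
      # relative gap between the merge heights bracketing a kk-cluster cut;
      # Ward heights grow with cluster size, so absolute gaps would be
      # biased toward small k
      top <- hh[nn - kk + 1L]
      bot <- if (nn - kk >= 1L) hh[nn - kk] else 0
      if (bot > 0) top / bot else Inf
    }, numeric(1))
    cand[which.max(gaps)]
  }
  if (is.null(k)) {
    # transient excursions (an exploratory glance, a saccade in flight)
    # are value outliers against each subject's local gaze course; despike
    # them before truncating so Ward's top merges reflect the sustained
    # regime structure, then reattach them to the nearest centroid
    spike <- rep(FALSE, n)
    if (n >= 21) {
      half_s <- min(61L, n - (1 - n %% 2))  # about 1 s of samples, odd
      for (j in seq_len(ncol(m))) {
        res <- m[, j] - stats::runmed(m[, j], k = half_s)
        thr <- max(spike_mads * stats::mad(res), 0.05)
        spike <- spike | abs(res) > thr
      }
    }
    core <- which(!spike)
    if (length(core) <= max(k_range) + 1L) core <- seq_len(n)
    hc_core <- if (length(core) < n) {
      hclust(dist(m[core, , drop = FALSE]), method = "ward.D2")
    } else hc
    if (length(core) < n) {
      k <- gap_rule(hc_core$height, length(core), k_range)
      assignments <- integer(n)
      assignments[core] <- cutree(hc_core, k = k)
      cents <- vapply(seq_len(k), function(cl) {
        colMeans(m[core[assignments[core] == cl], , drop = FALSE])
      }, numeric(ncol(m)))
      if (is.null(dim(cents))) cents <- matrix(cents, nrow = 1L)
      for (i in setdiff(seq_len(n), core)) {
        assignments[i] <- which.min(colSums((cents - m[i, ])^2))
      }
    } else {
      k <- gap_rule(h, n, k_range)
      assignments <- cutree(hc, k = k)
    }
  } else {
    assignments <- if (k == 1) rep(1L, n) else cutree(hc, k = k)
  }
  vd <- variance_decomposition(m, assignments)
  co <- central_objects(m, assignments)
  structure(list(assignments = assignments, k = as.integer(k),
                 within_class_pct = vd$within_class_pct,
                 between_class_pct = vd$between_class_pct,
                 dissimilarity = dissimilarity_summary(m, assignments),
                 central_objects = co,
                 time_centroids = co$t_s,
                 heights = h, hclust = hc),
            class = "cluster_result")
}

#' Within- and between-class variance percentages
#'
#' ANOVA-style decomposition of the total sum of squares of the time rows:
#' within = sum over clusters of squared distances to the cluster mean row,
#' between = sum over clusters of the cluster size times the squared
#' distance from cluster mean to grand mean. Reported as percentages of the
#' total, which they partition exactly.
#'
#' @param m Time-by-subject matrix.
#' @param assignments Cluster label per row.
#' @return List with `within_class_pct`, `between_class_pct`, `total_ss` and
#'   logical `degenerate` (TRUE when all rows are identical; both
#'   percentages are then 0).
#' @export
variance_decomposition <- function(m, assignments) {
  m <- as.matrix(m)
  stopifnot(length(assignments) == nrow(m))
  grand <- colMeans(m)
  total <- sum(sweep(m, 2, grand)^2)
  if (total <= 0) {
    return(list(within_class_pct = 0, between_class_pct = 0,
                total_ss = 0, degenerate = TRUE))
  }
  within <- 0
  between <- 0
  for (cl in unique(assignments)) {
    rows <- m[assignments == cl, , drop = FALSE]
    mu <- colMeans(rows)
    within <- within + sum(sweep(rows, 2, mu)^2)
    between <- between + nrow(rows) * sum((mu - grand)^2)
  }
  list(within_class_pct = 100 * within / total,
       between_class_pct = 100 * between / total,
       total_ss = total, degenerate = FALSE)
}

#' Central objects and time centroids
#'
#' For every cluster, the actually observed time row closest (Euclidean) to
#' the cluster mean: the most statistically representative time point of the
#' cluster, with its per-subject gaze values. Ties go to the earliest
#' timestamp.
#'
#' @param m Time-by-subject matrix (with optional `t_s` attribute; row index
#'   is used as the timestamp otherwise).
#' @param assignments Cluster label per row.
#' @return List with `cluster` (labels), `row` (row indices), `t_s` (time
#'   centroids) and `gaze` (k x subjects matrix of the central rows).
#' @export
central_objects <- function(m, assignments) {
  m <- as.matrix(m)
  t_s <- attr(m, "t_s") %||% (seq_len(nrow(m)) - 1L)
  cls <- sort(unique(assignments))
  rows <- integer(length(cls))
  for (i in seq_along(cls)) {
    idx <- which(assignments == cls[i])
    mu <- colMeans(m[idx, , drop = FALSE])
    d2 <- rowSums(sweep(m[idx, , drop = FALSE], 2, mu)^2)
    rows[i] <- idx[which.min(d2)]  # which.min returns the earliest tie
  }
  gaze <- m[rows, , drop = FALSE]
  rownames(gaze) <- paste0("cluster", cls)
  list(cluster = cls, row = rows, t_s = t_s[rows], gaze = gaze)
}

#' Dissimilarity of a clustering
#'
#' Mean pairwise Euclidean distance between cluster centroid rows; a single
#' summary of how far apart the gaze regimes of a window sit. Undefined
#' (NA) for a single cluster.
#'
#' @param m Time-by-subject matrix.
#' @param assignments Cluster label per row.
#' @return A single number, or NA with a warning when fewer than 2 clusters.
#' @export
dissimilarity_summary <- function(m, assignments) {
  m <- as.matrix(m)
  cls <- sort(unique(assignments))
  if (length(cls) < 2) {
    warning("dissimilarity undefined for a single cluster")
    return(NA_real_)
  }
  cent <- t(vapply(cls, function(cl) {
    colMeans(m[assignments == cl, , drop = FALSE])
  }, numeric(ncol(m))))
  mean(dist(cent))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Ward time clustering: k = %d, within %.1f%%, between %.1f%%, dissimilarity %.4f\n",
    x$k, x$within_class_pct, x$between_class_pct, x$dissimilarity))
  cat("time centroids (s):", paste(signif(x$time_centroids, 5),
                                   collapse = ", "), "\n")
  invisible(x)
}
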