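#' Register the core template onto one frame's point cloud by RANSAC
#'
#' Hypothesizes a translation from a single random template-point /
#' frame-point correspondence, scores it by the number of frame points
#' within `inlier_tol` of a translated template point (nearest neighbour),
#' keeps the consensus-maximal model and refits it by least squares on the
#' inlier correspondences. Sampling stops early once the standard adaptive
#' criterion (99.9% confidence at the current inlier rate) is met. A warm
#' start (`init`) — typically the previous frame's estimate — is scored
#' first and, if it already explains `accept_frac` of the frame points,
#' accepted without sampling.
#'
#' @param template Data.frame/matrix of template points (`x`, `y`).
#' @param frame Data.frame/matrix of candidate frame points (`x`, `y`).
#' @param n_iter Maximum RANSAC iterations (default 500).
#' @param inlier_tol Inlier distance tolerance in normalized units
#'   (default 0.005).
#' @param min_inlier_frac Quality floor on the inlier fraction of frame
#'   points (default 0.3); below it the frame is flagged low-quality.
#' @param seed Optional seed for reproducible sampling.
#' @param init Optional warm-start translation `c(tx, ty)`.
#' @param accept_frac Inlier fraction at which a warm start is accepted
#'   without sampling (default 0.5).
#' @return List with `tx`, `ty`, `n_inliers`, `inlier_frac`, `edge_x`
#'   (translated template bounding-box x-maximum), `bbox`, `ok`.
#' @export
#' @examples
#' tpl <- data.frame(x = c(0, .1, .2), y = c(0, .1, 0))
#' fr <- data.frame(x = tpl$x + 0.1, y = tpl$y)
#' ransac_register(tpl, fr, seed = 1)$tx
ransac_register <- function(template, frame, n_iter = 500,
                            inlier_tol = 0.005, min_inlier_frac = 0.3,
                            seed = NULL, init = NULL, accept_frac = 0.5) {
  tx_pts <- as.matrix(as.data.frame(template)[, c("x", "y")])
  fx_pts <- as.matrix(as.data.frame(frame)[, c("x", "y")])
  n_t <- nrow(tx_pts)
  n_f <- nrow(fx_pts)
  if (n_t < 3) stop("template needs at least 3 points", call. = FALSE)
  if (n_f < 1) stop("frame has no candidate points", call. = FALSE)
  tol2 <- inlier_tol^2
  # Dx[i, j] = frame_x[i] - template_x[j]: every entry is a candidate tx
  Dx <- outer(fx_pts[, 1], tx_pts[, 1], "-")
  Dy <- outer(fx_pts[, 2], tx_pts[, 2], "-")
  score <- function(tt) {
    d2 <- (Dx - tt[1])^2 + (Dy - tt[2])^2
    nn <- max.col(-d2, ties.method = "first")
    d2min <- d2[cbind(seq_len(n_f), nn)]
    inl <- which(d2min < tol2)
    list(n = length(inl), inliers = inl, nn = nn[inl])
  }
  refit <- function(sc) {
    if (sc$n == 0) return(NULL)
    tt <- c(mean(fx_pts[sc$inliers, 1] - tx_pts[sc$nn, 1]),
            mean(fx_pts[sc$inliers, 2] - tx_pts[sc$nn, 2]))
    list(tt = tt, sc = score(tt))
  }
  best <- NULL
  if (!is.null(init)) {
    sc <- score(init)
    best <- list(tt = init, sc = sc)
    if (sc$n / n_f >= accept_frac) {
      rf <- refit(sc)
      if (!is.null(rf) && rf$sc$n >= sc$n) best <- rf
      return(finish_registration(best, tx_pts, n_f, min_inlier_frac))
    }
  }
  run <- function() {
    b <- best
    it <- 0L
    needed <- n_iter
    while (it < min(n_iter, needed)) {
      it <- it + 1L
      i <- sample.int(n_f, 1L)
      j <- sample.int(n_t, 1L)
      tt <- c(unname(Dx[i, j]), unname(Dy[i, j]))
      sc <- score(tt)
      if (is.null(b) || sc$n > b$sc$n) {
        b <- list(tt = tt, sc = sc)
        # success prob of one draw: pick an inlier frame point (w) and its
        # true template partner (1/n_t)
        p <- max(sc$n / n_f, 1e-9) / n_t
        needed <- ceiling(log(1e-3) / log(max(1 - p, 1e-12)))
      }
    }
    b
  }
  best <- if (is.null(seed)) run() else with_seed(seed, run())
  rf <- refit(best$sc)
  if (!is.null(rf) && rf$sc$n >= best$sc$n) best <- rf
  finish_registration(best, tx_pts, n_f, min_inlier_frac)
}

finish_registration <- function(best, tx_pts, n_f, min_inlier_frac) {
  frac <- best$sc$n / n_f
  tt <- unname(best$tt)
  bbox <- c(xmin = min(tx_pts[, 1]) + tt[1],
            xmax = max(tx_pts[, 1]) + tt[1],
            ymin = min(tx_pts[, 2]) + tt[2],
            ymax = max(tx_pts[, 2]) + tt[2])
  list(tx = tt[1], ty = tt[2], n_inliers = best$sc$n,
       inlier_frac = frac, edge_x = max(tx_pts[, 1]) + tt[1], bbox = bbox,
       ok = frac >= min_inlier_frac)
}

#' Track the working edge across a frame sequence
#'
#' Runs per-frame RANSAC registration in time order, warm-starting each
#' frame with the previous estimate. Low-quality frames (inlier fraction
#' below the floor) get their `edge_x` linearly interpolated from
#' neighbouring good frames. If every frame fails, the trajectory is
#' returned fully flagged with `edge_x` missing.
#'
#' @param template Template point cloud (`x`, `y`).
#' @param frames Long data.frame of frame points (`frame`, `t_s`, `x`, `y`).
#' @param n_iter,inlier_tol,min_inlier_frac See [ransac_register()].
#' @param seed Root seed; each frame draws a seed derived from it and the
#'   frame index.
#' @return A data.frame of class `edge_trajectory` (`frame`, `t_s`, `tx`,
#'   `ty`, `edge_x`, `inlier_frac`, `ok`, `interpolated`), with attribute
#'   `bad_frac`.
#' @export
track_edge <- function(template, frames, n_iter = 500, inlier_tol = 0.005,
                       min_inlier_frac = 0.3, seed = 1) {
  ids <- sort(unique(frames$frame))
  split_pts <- split(frames, factor(frames$frame, levels = ids))
  n <- length(ids)
  out <- data.frame(frame = ids,
                    t_s = vapply(split_pts, function(d) d$t_s[1], numeric(1)),
                    tx = NA_real_, ty = NA_real_, edge_x = NA_real_,
                    inlier_frac = NA_real_, ok = FALSE, interpolated = FALSE)
  prev <- NULL
  for (i in seq_len(n)) {
    fit <- ransac_register(template, split_pts[[i]], n_iter = n_iter,
                           inlier_tol = inlier_tol,
                           min_inlier_frac = min_inlier_frac,
                           seed = derive_seed(seed, 2000L + ids[i]),
                           init = prev)
    out$tx[i] <- fit$tx
    out$ty[i] <- fit$ty
    out$inlier_frac[i] <- fit$inlier_frac
    out$ok[i] <- fit$ok
    if (fit$ok) {
      out$edge_x[i] <- fit$edge_x
      prev <- c(fit$tx, fit$ty)
    } else {
      prev <- NULL
    }
  }
  bad <- !out$ok
  if (any(bad) && any(!bad)) {
    out$edge_x[bad] <- approx(out$frame[!bad], out$edge_x[!bad],
                              xout = out$frame[bad], rule = 2)$y
    out$interpolated[bad] <- TRUE
  }
  attr(out, "bad_frac") <- mean(bad)
  class(out) <- c("edge_trajectory", class(out))
  out
}

#' Signed gaze distances from the working edge at time centroids
#'
#' For every subject-level central object, subtracts the working-edge
#' x-coordinate at the nearest tracked frame from the central object's gaze
#' position; positive values mean gaze right of the edge.
#'
#' @param centroids Data.frame with columns `t_centroid`, `gaze_x` and any
#'   identifier columns (`subject`, `session`, `window`, `cluster`, ...).
#' @param trajectory An `edge_trajectory` from [track_edge()] (or any
#'   data.frame with `t_s` and `edge_x`).
#' @param max_gap_s Maximum tolerated distance to the nearest frame
#'   (default 0.1 s).
#' @return `centroids` with added columns `edge_x` and `distance`
#'   (`gaze_x - edge_x`).
#' @export
centroid_distances <- function(centroids, trajectory, max_gap_s = 0.1) {
  stopifnot(all(c("t_centroid", "gaze_x") %in% names(centroids)))
  tt <- trajectory$t_s
  if (length(tt) == 0 || all(is.na(trajectory$edge_x))) {
    stop("edge trajectory has no usable frames", call. = FALSE)
  }
  idx <- vapply(centroids$t_centroid, function(t0) which.min(abs(tt - t0)),
                integer(1))
  gap <- abs(tt[idx] - centroids$t_centroid)
  if (any(gap > max_gap_s)) {
    b <- which(gap > max_gap_s)[1]
    stop(sprintf("no frame within %.3f s of centroid at t = %.3f s",
                 max_gap_s, centroids$t_centroid[b]), call. = FALSE)
  }
  centroids$edge_x <- trajectory$edge_x[idx]
  centroids$distance <- centroids$gaze_x - centroids$edge_x
  centroids
}

#' Edge-referenced spatial dispersion per subject and window
#'
#' Summarises a window's centroid distances per subject: the mean signed
#' distance and the "edge variability" — the sample SD of the distances
#' across the window's time centroids. With fewer than two centroids the SD
#' is reported missing while the mean is kept.
#'
#' @param records Output of [centroid_distances()] with `subject`,
#'   `session`, `window`, `distance` columns.
#' @return Data.frame (`subject`, `session`, `window`, `n_centroids`,
#'   `mean_distance`, `edge_variability`).
#' @export
spatial_dispersion <- function(records) {
  stopifnot(all(c("subject", "session", "window", "distance")
                %in% names(records)))
  key <- interaction(records$subject, records$session, records$window,
                     drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(subject = d$subject[1], session = d$session[1],
               window = d$window[1], n_centroids = nrow(d),
               mean_distance = mean(d$distance),
               edge_variability = if (nrow(d) >= 2) sd(d$distance)
                                  else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
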