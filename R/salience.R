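#' Build the binary subject-by-time press matrix
#'
#' Button-press latencies are rounded to the nearest second (half-up) and
#' entered into a discrete subject x time matrix with 1 for a press and 0
#' for no response; multiple presses by one subject within one second
#' collapse to a single 1.
#'
#' @param presses A data.frame with columns `subject` and `latency_s`
#'   (seconds, continuous). Additional columns are ignored; to pool
#'   assessments, pre-compose the `subject` key (e.g. `"S01|Pre"`).
#' @param duration_s Video duration in seconds (number of matrix columns).
#' @param subjects Optional character vector fixing row order (and including
#'   subjects who never pressed); defaults to sorted unique subjects in
#'   `presses`.
#' @return An integer 0/1 matrix, rows named by subject, columns `0 ..
#'   duration_s - 1`.
#' @export
#' @examples
#' p <- data.frame(subject = "A", latency_s = c(2.4, 2.6))
#' m <- build_press_matrix(p, duration_s = 5)
#' which(m["A", ] == 1)  # seconds 2 and 3
build_press_matrix <- function(presses, duration_s, subjects = NULL) {
  stopifnot(is.data.frame(presses),
            all(c("subject", "latency_s") %in% names(presses)))
  stop_if_not_number(duration_s, "duration_s", lower = 1)
  bad <- which(presses$latency_s < 0 | presses$latency_s > duration_s)
  if (length(bad) > 0) {
    stop(sprintf(
      "latency outside [0, %s]: subject %s, value %.3f", duration_s,
      presses$subject[bad[1]], presses$latency_s[bad[1]]), call. = FALSE)
  }
  subjects <- subjects %||% sort(unique(as.character(presses$subject)))
  T_s <- as.integer(duration_s)
  m <- matrix(0L, nrow = length(subjects), ncol = T_s,
              dimnames = list(subjects, as.character(seq_len(T_s) - 1L)))
  if (nrow(presses) > 0) {
    # round half-up, clamp the boundary latency == duration into the last bin
    sec <- pmin(floor(presses$latency_s + 0.5), T_s - 1L)
    ri <- match(as.character(presses$subject), subjects)
    if (anyNA(ri)) stop("press log contains subjects not in `subjects`",
                        call. = FALSE)
    m[cbind(ri, sec + 1L)] <- 1L
  }
  m
}

#' Per-subject press counts by action phase
#'
#' Segments the press matrix by the per-second phase annotation and sums
#' presses per subject within each phase; also returns the across-subject
#' mean count per phase (the descriptive statistic used to identify the most
#' salient phase).
#'
#' @param matrix Press matrix from [build_press_matrix()].
#' @param track Phase track data.frame with a `phase` column of the same
#'   length as `ncol(matrix)`.
#' @return A list with `counts` (subject x phase integer matrix over the six
#'   phases) and `phase_means` (named numeric).
#' @export
phase_press_counts <- function(matrix, track) {
  phase <- as.character(track$phase)
  if (length(phase) != ncol(matrix)) {
    stop("phase track length must equal press-matrix width", call. = FALSE)
  }
  counts <- sapply(ACTION_PHASES, function(ph) {
    cols <- phase == ph
    if (!any(cols)) return(rep(0L, nrow(matrix)))
    as.integer(rowSums(matrix[, cols, drop = FALSE]))
  })
  if (is.null(dim(counts))) counts <- t(counts)  # single-subject matrix
  rownames(counts) <- rownames(matrix)
  list(counts = counts, phase_means = colMeans(counts))
}

#' Sliding-window press probability series
#'
#' For each 10-s window (5-s slide by default) the probability of a
#' meaningful event is the fraction of subjects with at least one press in
#' the window; a subject counts at most once per window. Windows advance
#' until the next window would extend past the video end (trailing partial
#' windows are dropped).
#'
#' @param matrix Press matrix from [build_press_matrix()].
#' @param window_s Window length in seconds (default 10).
#' @param slide_s Slide increment in seconds (default 5).
#' @return A data.frame (`window_start_s`, `window_end_s`, `probability`)
#'   with attributes `window_s` and `slide_s`.
#' @export
salience_series <- function(matrix, window_s = 10, slide_s = 5) {
  if (!is.matrix(matrix) || nrow(matrix) == 0 || ncol(matrix) == 0) {
    stop("press matrix must be non-empty", call. = FALSE)
  }
  stop_if_not_number(window_s, "window_s", lower = 1e-9)
  stop_if_not_number(slide_s, "slide_s", lower = 1e-9)
  if (slide_s > window_s) stop("window_s must be >= slide_s", call. = FALSE)
  T_s <- ncol(matrix)
  starts <- seq(0L, T_s - window_s, by = slide_s)
  # cumulative row sums give O(1) per-window any-press lookups
  cs <- cbind(0L, t(apply(matrix, 1, cumsum)))
  prob <- vapply(starts, function(s) {
    n_press <- cs[, s + window_s + 1L] - cs[, s + 1L]
    mean(n_press > 0)
  }, numeric(1))
  out <- data.frame(window_start_s = starts,
                    window_end_s = starts + window_s,
                    probability = prob)
  attr(out, "window_s") <- window_s
  attr(out, "slide_s") <- slide_s
  out
}

# majority phase of [start, end); ties broken by earliest occurrence in window
dominant_phase <- function(track, start_s, end_s) {
  ph <- as.character(track$phase[(start_s + 1L):min(end_s, nrow(track))])
  tab <- table(ph)
  top <- names(tab)[tab == max(tab)]
  ph[ph %in% top][1L]
}

#' Select meaningful analysis windows
#'
#' Retains windows whose press probability reaches the given percentile of
#' the probability series (type-7 quantile) and whose dominant phase matches
#' the requested phase, then merges overlapping retained windows into
#' maximal runs so gaze samples are not double-counted. Both the unmerged
#' windows and the merged runs are returned.
#'
#' @param series Output of [salience_series()].
#' @param track Phase track covering the same video.
#' @param percentile Threshold percentile of the probability series
#'   (default 90).
#' @param phase Required dominant phase (default `"core_move"`).
#' @return An object of class `meaningful_windows`: list with `windows`
#'   (retained, unmerged), `merged` (maximal runs with recomputed dominant
#'   phase and the max member probability), `threshold`, `percentile`,
#'   `phase`.
#' @export
select_windows <- function(series, track, percentile = 90,
                           phase = "core_move") {
  stop_if_not_number(percentile, "percentile", lower = 0, upper = 100)
  threshold <- as.numeric(quantile(series$probability, percentile / 100,
                                   type = 7, names = FALSE))
  cand <- series[series$probability >= threshold, , drop = FALSE]
  if (nrow(cand) > 0) {
    dom <- vapply(seq_len(nrow(cand)), function(i) {
      dominant_phase(track, cand$window_start_s[i], cand$window_end_s[i])
    }, character(1))
    cand <- cand[dom == phase, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    warning("no window reaches the ", percentile,
            "th percentile with dominant phase '", phase, "'")
    merged <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         dominant_phase = character(0),
                         probability = numeric(0))
    windows <- cbind(cand, dominant_phase = character(0))
  } else {
    cand <- cand[order(cand$window_start_s), , drop = FALSE]
    windows <- data.frame(start_s = cand$window_start_s,
                          end_s = cand$window_end_s,
                          dominant_phase = phase,
                          probability = cand$probability)
    grp <- cumsum(c(1, as.integer(
      windows$start_s[-1] >= cummax(windows$end_s[-nrow(windows)]))))
    merged <- do.call(rbind, lapply(split(windows, grp), function(d) {
      data.frame(start_s = min(d$start_s), end_s = max(d$end_s),
                 dominant_phase = dominant_phase(track, min(d$start_s),
                                                 max(d$end_s)),
                 probability = max(d$probability))
    }))
    rownames(merged) <- NULL
  }
  structure(list(windows = windows, merged = merged, threshold = threshold,
                 percentile = percentile, phase = phase),
            class = "meaningful_windows")
}

#' @export
print.meaningful_windows <- function(x, ...) {
  cat(sprintf(
    "meaningful windows: %d retained (%d merged runs), threshold %.3f (%gth pct), phase %s\n",
    nrow(x$windows), nrow(x$merged), x$threshold, x$percentile, x$phase))
  invisible(x)
}
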