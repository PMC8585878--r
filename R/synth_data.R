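#' Generate the per-second action-phase track
#'
#' Each second of the demonstration video carries exactly one of the six
#' action-phase labels (core reposition, core move, light percussion,
#' percussion, grinding, tool change). Segments are drawn phase-by-phase:
#' the phase from `phase_weights`, the segment length from a shifted Poisson
#' with the configured mean. An explicit `phase_layout` in the configuration
#' bypasses the stochastic model entirely.
#'
#' @param cfg A [synth_config()].
#' @return A data.frame with columns `second` (0-based) and `phase`, one row
#'   per second, plus a `"segments"` attribute (`phase`, `start_s`, `len_s`).
#' @export
generate_phase_track <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  T_s <- cfg$video_duration_s
  if (!is.null(cfg$phase_layout)) {
    segs <- data.frame(phase = as.character(cfg$phase_layout$phase),
                       len_s = as.integer(cfg$phase_layout$len_s))
  } else {
    phases <- names(cfg$phase_weights)
    w <- cfg$phase_weights / sum(cfg$phase_weights)
    segs <- with_seed(derive_seed(cfg$seed, 1L), {
      out_phase <- character(0)
      out_len <- integer(0)
      total <- 0L
      while (total < T_s) {
        ph <- sample(phases, 1L, prob = w)
        len <- 1L + rpois(1L, max(cfg$phase_mean_len_s[[ph]] - 1, 0))
        len <- min(len, T_s - total)
        out_phase <- c(out_phase, ph)
        out_len <- c(out_len, len)
        total <- total + len
      }
      data.frame(phase = out_phase, len_s = out_len)
    })
  }
  segs$start_s <- cumsum(c(0L, segs$len_s))[seq_len(nrow(segs))]
  track <- data.frame(
    second = seq_len(T_s) - 1L,
    phase = rep(segs$phase, segs$len_s)
  )
  attr(track, "segments") <- segs
  track
}

# onsets (s) of the salient-phase segments in a phase track
salient_onsets <- function(track, salient_phase) {
  segs <- attr(track, "segments")
  if (is.null(segs)) {
    r <- rle(as.character(track$phase))
    segs <- data.frame(phase = r$values, len_s = r$lengths)
    segs$start_s <- cumsum(c(0L, r$lengths))[seq_along(r$values)]
  }
  segs$start_s[segs$phase == salient_phase]
}

#' Generate button-press logs locked to salient phase onsets
#'
#' Subjects press for events they perceive as meaningful. The generator
#' plants presses at onsets of the salient phase (core moves by default):
#' each subject responds to each onset with probability
#' `press_response_prob`, after a truncated-normal reaction lag. Spontaneous
#' false-alarm presses occur as a Poisson background.
#'
#' @param cfg A [synth_config()].
#' @param track Phase track from [generate_phase_track()].
#' @return A data.frame (`subject`, `session`, `latency_s`), latencies sorted
#'   within subject and session and clipped to `[0, video_duration_s]`.
#' @export
generate_presses <- function(cfg, track) {
  cfg <- validate_synth_config(cfg)
  onsets <- salient_onsets(track, cfg$salient_phase)
  subj <- subject_ids(cfg)
  T_s <- cfg$video_duration_s
  with_seed(derive_seed(cfg$seed, 2L), {
    rows <- vector("list", length(cfg$sessions) * length(subj))
    i <- 0L
    for (sess in cfg$sessions) {
      for (s in subj) {
        hit <- onsets[runif(length(onsets)) < cfg$press_response_prob]
        lag <- pmax(rnorm(length(hit), cfg$press_lag_mean_s,
                          cfg$press_lag_sd_s), 0)
        lat <- hit + lag
        n_bg <- rpois(1L, cfg$press_background_rate_hz * T_s)
        lat <- c(lat, runif(n_bg, 0, T_s))
        lat <- sort(pmin(pmax(lat, 0), T_s))
        i <- i + 1L
        rows[[i]] <- if (length(lat) > 0) {
          data.frame(subject = s, session = sess, latency_s = lat)
        } else NULL
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(subject = character(0), session = character(0),
                        latency_s = numeric(0))
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate the working-edge trajectory
#'
#' The core sits at a rest position until the demonstrator repositions it,
#' so the working edge (the core's right-most x coordinate) follows a
#' piecewise-constant step process — a new level roughly every
#' `edge_step_period_s` seconds — plus a small sinusoidal wobble.
#'
#' @param cfg A [synth_config()].
#' @return A data.frame (`frame`, `t_s`, `edge_x`) at `frame_rate_hz`.
#' @export
generate_edge_truth <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  fps <- cfg$frame_rate_hz
  n_frames <- as.integer(round(cfg$video_duration_s * fps))
  t <- (seq_len(n_frames) - 1L) / fps
  with_seed(derive_seed(cfg$seed, 3L), {
    n_lev <- ceiling(cfg$video_duration_s / cfg$edge_step_period_s) + 1L
    levels <- if (!is.null(cfg$edge_level_values)) {
      rep_len(cfg$edge_level_values, n_lev)
    } else {
      pmin(pmax(rnorm(n_lev, cfg$edge_base, cfg$edge_level_sd), 0.35), 0.85)
    }
    idx <- floor(t / cfg$edge_step_period_s) + 1L
    edge <- levels[idx] +
      cfg$edge_wobble_amp * sin(2 * pi * t / cfg$edge_wobble_period_s)
    data.frame(frame = seq_len(n_frames) - 1L, t_s = t,
               edge_x = pmin(pmax(edge, 0), 1))
  })
}

#' Generate the core template point cloud
#'
#' A fixed cloud of feature points standing in for the features a computer
#' vision detector would extract from a screenshot of the core. The cloud's
#' bounding-box x-maximum defines the working edge in template coordinates.
#'
#' @param cfg A [synth_config()].
#' @return A data.frame (`x`, `y`) in normalized units with a `"bbox"`
#'   attribute `c(xmin, xmax, ymin, ymax)`.
#' @export
generate_template <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  with_seed(derive_seed(cfg$seed, 4L), {
    n <- cfg$n_template_points
    tpl <- data.frame(x = runif(n, 0, 0.22), y = runif(n, 0, 0.30))
    attr(tpl, "bbox") <- c(xmin = min(tpl$x), xmax = max(tpl$x),
                           ymin = min(tpl$y), ymax = max(tpl$y))
    tpl
  })
}

#' Generate per-frame feature-point clouds
#'
#' Each video frame carries the template cloud translated so its bounding-box
#' x-maximum coincides with the true working edge, perturbed by per-point
#' measurement noise, plus a configured fraction of uniformly scattered
#' outlier points. Each frame's randomness is seeded from the root seed and
#' the frame index, so any subset of frames is reproducible independently of
#' which other frames are generated.
#'
#' @param cfg A [synth_config()].
#' @param edge_truth Trajectory from [generate_edge_truth()].
#' @param template Template from [generate_template()]; regenerated if NULL.
#' @param frames Optional integer vector of frame indices (0-based); default
#'   all frames in `edge_truth`.
#' @return A data.frame (`frame`, `t_s`, `point_id`, `x`, `y`, `true_inlier`);
#'   `true_inlier` is synthetic ground truth, not available for real data.
#' @export
generate_frame_points <- function(cfg, edge_truth, template = NULL,
                                  frames = NULL) {
  cfg <- validate_synth_config(cfg)
  template <- template %||% generate_template(cfg)
  keep <- if (is.null(frames)) edge_truth$frame else intersect(frames, edge_truth$frame)
  et <- edge_truth[match(keep, edge_truth$frame), ]
  n_in <- nrow(template)
  n_out <- round(cfg$outlier_frac / (1 - cfg$outlier_frac) * n_in)
  tpl_xmax <- max(template$x)
  res <- vector("list", nrow(et))
  for (i in seq_len(nrow(et))) {
    fr <- et$frame[i]
    with_seed(derive_seed(cfg$seed, 1000L + fr), {
      tx <- et$edge_x[i] - tpl_xmax
      ty <- 0.30 + 0.02 * sin(2 * pi * et$t_s[i] / 60)
      x <- template$x + tx + rnorm(n_in, 0, cfg$point_jitter_sd)
      y <- template$y + ty + rnorm(n_in, 0, cfg$point_jitter_sd)
      if (n_out > 0) {
        x <- c(x, runif(n_out))
        y <- c(y, runif(n_out))
      }
      res[[i]] <- data.frame(
        frame = fr, t_s = et$t_s[i],
        point_id = seq_along(x) - 1L,
        x = pmin(pmax(x, 0), 1), y = pmin(pmax(y, 0), 1),
        true_inlier = c(rep(TRUE, n_in), rep(FALSE, n_out))
      )
    })
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# latent subject factors: aptitude plus a gaze factor correlated with it
generate_latent <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 0L), {
    z <- rnorm(cfg$n_subjects)
    eps <- rnorm(cfg$n_subjects)
    rho <- cfg$latent_coupling
    data.frame(
      subject = subject_ids(cfg),
      aptitude = z,
      gaze_factor = rho * z + sqrt(1 - rho^2) * eps
    )
  })
}

# per-session TIME fraction spent in exploratory glances, moment-matched so
# the overall gaze x dispersion hits the configured CV target: the target
# variance minus what edge steps, fixation offsets, jitter and the
# re-foveation lag already supply, divided by the variance a glance adds
explore_time_frac <- function(cfg, session_index) {
  m <- cfg$edge_base + cfg$gaze_offset_mean
  lag_frac <- min(cfg$track_lag_s_by_session[session_index] /
                    cfg$edge_step_period_s, 0.8)
  v_lev <- if (!is.null(cfg$edge_level_values)) {
    v <- cfg$edge_level_values
    mean((v - mean(v))^2)
  } else cfg$edge_level_sd^2
  v_base <- v_lev +
    cfg$edge_offset_sd_by_session[session_index]^2 + cfg$jitter_sd^2 +
    lag_frac * 2 * v_lev
  v_target <- (cfg$gaze_cv_by_session[session_index] * m)^2
  v_explore <- cfg$explore_sd^2 + (cfg$explore_center - m)^2
  min(max((v_target - v_base) / v_explore, 0), 0.8)
}

# convert a target glance TIME fraction into the probability that an edge
# fixation is followed by one glance (glances never chain, so a viewing
# cycle is one edge fixation plus at most one glance)
explore_fix_prob <- function(cfg, time_frac) {
  mu_e <- cfg$explore_dur_shape / cfg$explore_dur_rate
  mu_f <- cfg$fix_dur_shape / cfg$fix_dur_rate
  if (time_frac <= 0) return(0)
  p <- time_frac * mu_f / (mu_e * (1 - time_frac))
  min(max(p, 0), 1)
}

#' Generate gaze streams
#'
#' Gaze is a two-state renewal process. Edge-locked fixations (Gamma
#' durations, ~0.5-s mean) anchor on the working edge plus a per-subject
#' offset drawn per fixation with the session's configured spread; brief
#' exploratory glances (~0.15-s mean) anchor elsewhere in the scene.
#' Saccades are instantaneous anchor jumps, and Gaussian jitter rides on
#' every sample. Two session-dependent behaviours distinguish novices from
#' trained observers: the glance time-fraction, moment-matched so the
#' overall x dispersion realizes the session's target coefficient of
#' variation, and a re-foveation lag — after the core is repositioned, the
#' edge-locked anchor catches up with the new edge position only after an
#' exponential per-reposition delay.
#'
#' @param cfg A [synth_config()].
#' @param track Phase track (carried for provenance; anchoring follows the
#'   edge trajectory, which moves during the whole demonstration).
#' @param edge_truth Trajectory from [generate_edge_truth()].
#' @param latent Latent factors from `generate_latent`; regenerated if NULL.
#' @return A data.frame (`subject`, `session`, `t_s`, `x`, `y`, `valid`) at
#'   `sample_rate_hz`, coordinates clipped to `[0, 1]`.
#' @export
generate_gaze <- function(cfg, track, edge_truth, latent = NULL) {
  cfg <- validate_synth_config(cfg)
  latent <- latent %||% generate_latent(cfg)
  fs <- cfg$sample_rate_hz
  n_samp <- as.integer(round(cfg$video_duration_s * fs))
  t <- (seq_len(n_samp) - 1L) / fs
  # reconstruct the rest-position levels and the wobble so a lagged version
  # of the step process can be tracked per subject
  step <- cfg$edge_step_period_s
  wobble_at <- function(tt) {
    cfg$edge_wobble_amp * sin(2 * pi * tt / cfg$edge_wobble_period_s)
  }
  n_seg <- ceiling(cfg$video_duration_s / step)
  seg_mid <- pmin((seq_len(n_seg) - 0.5) * step, max(edge_truth$t_s))
  fi <- pmax(findInterval(seg_mid, edge_truth$t_s), 1L)
  levels <- edge_truth$edge_x[fi] - wobble_at(edge_truth$t_s[fi])
  boundaries <- (seq_len(n_seg) - 1L) * step  # boundaries[1] == 0
  subj <- subject_ids(cfg)
  out <- vector("list", length(cfg$sessions) * length(subj))
  i <- 0L
  with_seed(derive_seed(cfg$seed, 5L), {
    for (si in seq_along(cfg$sessions)) {
      sess <- cfg$sessions[si]
      p_exp <- explore_fix_prob(cfg, explore_time_frac(cfg, si))
      off_sd <- cfg$edge_offset_sd_by_session[si]
      lag_mean <- cfg$track_lag_s_by_session[si]
      for (sj in seq_along(subj)) {
        g <- latent$gaze_factor[sj]
        mu_s <- cfg$gaze_offset_mean + cfg$aptitude_offset_gain * g
        sd_s <- off_sd * exp(0.25 * g)
        # subject's lagged view of the step process
        delays <- if (lag_mean > 0) {
          pmin(stats::rexp(n_seg, 1 / lag_mean), 0.8 * step)
        } else rep(0, n_seg)
        switch_t <- boundaries[-1] + delays[-1]
        lagged_level_at <- function(tt) {
          levels[findInterval(tt, switch_t) + 1L]
        }
        # alternating renewal: an edge fixation, then at most one glance
        mean_cycle <- cfg$fix_dur_shape / cfg$fix_dur_rate +
          p_exp * cfg$explore_dur_shape / cfg$explore_dur_rate
        n_guess <- ceiling(cfg$video_duration_s / mean_cycle) + 50L
        repeat {
          glance_after <- runif(n_guess) < p_exp
          fix_durs <- rgamma(n_guess, cfg$fix_dur_shape, cfg$fix_dur_rate)
          gl_durs <- pmin(rgamma(n_guess, cfg$explore_dur_shape,
                                 cfg$explore_dur_rate),
                          cfg$explore_dur_max_s)
          if (sum(fix_durs) + sum(gl_durs[glance_after]) >=
                cfg$video_duration_s) break
          n_guess <- n_guess * 2L
        }
        # interleave cycles into one fixation sequence
        n_ep <- n_guess + sum(glance_after)
        explore <- logical(n_ep)
        durs <- numeric(n_ep)
        pos <- cumsum(1L + as.integer(glance_after))  # index of each cycle end
        fix_idx <- pos - as.integer(glance_after)
        durs[fix_idx] <- fix_durs
        durs[pos[glance_after]] <- gl_durs[glance_after]
        explore[pos[glance_after]] <- TRUE
        starts <- cumsum(c(0, durs))
        nf <- which(starts >= cfg$video_duration_s)[1L]
        starts <- starts[seq_len(nf)]
        explore <- explore[seq_len(nf)]
        offs <- rnorm(nf, mu_s, sd_s)
        abs_anchor <- rnorm(nf, cfg$explore_center, cfg$explore_sd)
        anchor_y <- rnorm(nf, 0.5, 0.05)
        fix_of_t <- findInterval(t, starts)
        x <- ifelse(explore[fix_of_t],
                    abs_anchor[fix_of_t],
                    lagged_level_at(t) + wobble_at(t) + offs[fix_of_t]) +
          rnorm(n_samp, 0, cfg$jitter_sd)
        y <- anchor_y[fix_of_t] + rnorm(n_samp, 0, cfg$jitter_sd)
        valid <- runif(n_samp) >= cfg$missing_rate
        i <- i + 1L
        out[[i]] <- data.frame(
          subject = subj[sj], session = sess, t_s = t,
          x = pmin(pmax(x, 0), 1), y = pmin(pmax(y, 0), 1),
          valid = valid
        )
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate the motor-performance table
#'
#' Handaxe scores rise along a saturating power curve in the square root of
#' practice hours; percussion error decays stepwise across assessments.
#' A subject's latent aptitude shifts both curves, and is correlated
#' (`latent_coupling`) with the same subject's gaze-offset factor, planting
#' the gaze-performance relationship the canonical correlation stage is
#' meant to recover.
#'
#' @param cfg A [synth_config()].
#' @param latent Latent factors from `generate_latent`; regenerated if NULL.
#' @return A data.frame (`subject`, `session`, `hours`, `handaxe_score`,
#'   `percussion_error`).
#' @export
generate_performance <- function(cfg, latent = NULL) {
  cfg <- validate_synth_config(cfg)
  latent <- latent %||% generate_latent(cfg)
  subj <- subject_ids(cfg)
  with_seed(derive_seed(cfg$seed, 6L), {
    rows <- vector("list", length(cfg$sessions))
    for (si in seq_along(cfg$sessions)) {
      h <- cfg$hours_by_session[si]
      mu_score <- cfg$perf_initial +
        (cfg$perf_asymptote - cfg$perf_initial) *
        (1 - exp(-cfg$perf_rate * sqrt(h)))
      mu_err <- cfg$percussion_start * cfg$percussion_step^(si - 1)
      rows[[si]] <- data.frame(
        subject = subj,
        session = cfg$sessions[si],
        hours = h,
        handaxe_score = mu_score + cfg$aptitude_score_gain * latent$aptitude +
          rnorm(length(subj), 0, cfg$perf_noise_sd),
        percussion_error = pmax(
          mu_err - cfg$aptitude_error_gain * latent$aptitude +
            rnorm(length(subj), 0, cfg$percussion_noise_sd), 0.05)
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic experiment
#'
#' Runs every generator under seeds derived from the configuration's root
#' seed, so the full dataset is a pure function of the configuration.
#'
#' @param cfg A [synth_config()].
#' @param frame_points One of `"none"` (default; generate lazily later via
#'   [generate_frame_points()]), `"all"`, or an integer vector of frame
#'   indices.
#' @return An object of class `synth_dataset`: a list with elements
#'   `phase_track`, `presses`, `gaze`, `edge_truth`, `template`,
#'   `frame_points` (possibly NULL), `performance`, `latent`, `config`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 3, video_duration_s = 64, seed = 2)
#' ds <- generate_dataset(cfg)
#' str(ds$performance)
generate_dataset <- function(cfg, frame_points = "none") {
  cfg <- validate_synth_config(cfg)
  latent <- generate_latent(cfg)
  track <- generate_phase_track(cfg)
  presses <- generate_presses(cfg, track)
  edge <- generate_edge_truth(cfg)
  template <- generate_template(cfg)
  gaze <- generate_gaze(cfg, track, edge, latent)
  perf <- generate_performance(cfg, latent)
  fp <- NULL
  if (identical(frame_points, "all")) {
    fp <- generate_frame_points(cfg, edge, template)
  } else if (is.numeric(frame_points)) {
    fp <- generate_frame_points(cfg, edge, template, frames = frame_points)
  }
  structure(list(phase_track = track, presses = presses, gaze = gaze,
                 edge_truth = edge, template = template, frame_points = fp,
                 performance = perf, latent = latent, config = cfg),
            class = "synth_dataset")
}

#' Write a synthetic dataset as plain CSV files
#'
#' Emits the pipeline's interchange formats: `gaze.csv`, `presses.csv`,
#' `phases.csv`, `performance.csv`, `edge.csv`, `template.csv` and (when
#' present) `frame_points.csv`, all UTF-8 with a header row and normalized
#' coordinates.
#'
#' @param ds A `synth_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_synth_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(ds$gaze, "gaze.csv")
  wr(ds$presses, "presses.csv")
  wr(ds$phase_track, "phases.csv")
  wr(ds$performance, "performance.csv")
  wr(ds$edge_truth, "edge.csv")
  wr(ds$template, "template.csv")
  if (!is.null(ds$frame_points)) {
    wr(ds$frame_points[c("frame", "point_id", "x", "y")], "frame_points.csv")
  }
  invisible(paths)
}
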