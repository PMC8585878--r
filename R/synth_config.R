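#' Configuration for a synthetic observation experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the study design the package targets: 11 participants watch the same
#' 1024-s (17 min 4 s) knapping demonstration at three assessments
#' (`Pre`, `Post1`, `Post2`, after 0 / 50 / 100 h of practice), gaze is
#' recorded at 60 Hz in normalized `[0,1]` screen coordinates, and video
#' frames carry feature-point clouds at 30 fps from which the core's working
#' edge is tracked.
#'
#' Session-level gaze structure is planted so the pipeline has a known truth
#' to recover: the per-session target coefficient of variation
#' (`gaze_cv_by_session`) decreases after training, while the per-session
#' spread of edge-referenced fixation offsets (`edge_offset_sd_by_session`)
#' increases at the final assessment. Subject-level aptitude is latently
#' coupled (correlation `latent_coupling`) to the subject's gaze offset
#' parameters, which is what the canonical correlation stage should detect.
#'
#' @param n_subjects Number of participants.
#' @param sessions Ordered assessment labels.
#' @param video_duration_s Video duration in seconds.
#' @param sample_rate_hz Gaze sampling rate (Hz).
#' @param frame_rate_hz Video frame rate for feature-point clouds (fps).
#' @param phase_weights Named sampling weights over the six action phases.
#' @param phase_mean_len_s Named mean segment length (s) per phase.
#' @param phase_layout Optional data.frame (`phase`, `len_s`) giving an
#'   explicit deterministic segment layout; lengths must sum to
#'   `video_duration_s`. Overrides the stochastic segment model.
#' @param salient_phase Phase whose segment onsets trigger button presses.
#' @param press_response_prob Per-subject probability of responding to a
#'   salient onset.
#' @param press_lag_mean_s,press_lag_sd_s Reaction-lag distribution
#'   (truncated normal, s).
#' @param press_background_rate_hz Rate of spontaneous false-alarm presses.
#' @param gaze_cv_by_session Target gaze coefficient of variation per session.
#' @param edge_offset_sd_by_session Target SD of the edge-referenced fixation
#'   offset per session (normalized units).
#' @param gaze_offset_mean Mean fixation offset relative to the working edge
#'   (negative = on the core body, left of its right-most edge).
#' @param fix_dur_shape,fix_dur_rate Gamma parameters of edge-locked fixation
#'   durations (defaults give a 0.5-s mean, typical of task viewing).
#' @param jitter_sd Within-fixation gaze jitter SD (normalized units).
#' @param explore_center,explore_sd Location and spread of off-core
#'   exploratory glances used to calibrate the overall CV.
#' @param explore_dur_shape,explore_dur_rate Gamma parameters of glance
#'   durations (defaults give a brief 0.15-s mean: exploratory sampling
#'   rather than sustained fixation).
#' @param explore_dur_max_s Hard cap on glance duration (s); anything longer
#'   would be a fixation, not a glance.
#' @param track_lag_s_by_session Mean re-foveation lag (s) after a core
#'   reposition, per session; novices catch up with the moved edge more
#'   slowly than trained observers.
#' @param edge_base Mean working-edge x position.
#' @param edge_level_sd SD of the core rest-position levels.
#' @param edge_level_values Optional vector of rest-position levels cycled
#'   deterministically instead of random draws — used to plant a known
#'   number of well-separated gaze regimes per analysis window.
#' @param edge_step_period_s Mean time between core repositions (s).
#' @param edge_wobble_amp,edge_wobble_period_s Small sinusoidal wobble on top
#'   of the step process.
#' @param n_template_points Feature points in the core template cloud.
#' @param outlier_frac Fraction of spurious feature points per frame.
#' @param point_jitter_sd Per-point measurement noise for inlier feature
#'   points.
#' @param hours_by_session Cumulative practice hours at each assessment.
#' @param perf_initial,perf_asymptote,perf_rate Power-curve parameters of the
#'   handaxe score: `initial + (asymptote - initial) * (1 - exp(-rate *
#'   sqrt(hours)))`.
#' @param perf_noise_sd Additive score noise SD.
#' @param percussion_start First-session mean percussion error.
#' @param percussion_step Multiplicative per-session decay of percussion
#'   error.
#' @param percussion_noise_sd Additive percussion-error noise SD.
#' @param aptitude_score_gain,aptitude_error_gain,aptitude_offset_gain Effect
#'   of a subject's latent aptitude on scores, errors and gaze offsets.
#' @param latent_coupling Correlation between latent aptitude and the
#'   subject's gaze-offset factor.
#' @param missing_rate Fraction of gaze samples flagged invalid.
#' @param seed Root RNG seed; the full dataset is a pure function of the
#'   configuration including this seed.
#' @return An object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 4, video_duration_s = 128, seed = 7)
#' cfg$sessions
synth_config <- function(n_subjects = 11,
                         sessions = c("Pre", "Post1", "Post2"),
                         video_duration_s = 1024,
                         sample_rate_hz = 60,
                         frame_rate_hz = 30,
                         phase_weights = c(core_reposition = 0.18,
                                           core_move = 0.30,
                                           light_percussion = 0.14,
                                           percussion = 0.20,
                                           grinding = 0.08,
                                           tool_change = 0.10),
                         phase_mean_len_s = c(core_reposition = 4,
                                              core_move = 8,
                                              light_percussion = 6,
                                              percussion = 10,
                                              grinding = 6,
                                              tool_change = 3),
                         phase_layout = NULL,
                         salient_phase = "core_move",
                         press_response_prob = 0.8,
                         press_lag_mean_s = 1.0,
                         press_lag_sd_s = 0.5,
                         press_background_rate_hz = 0.002,
                         gaze_cv_by_session = c(0.20, 0.11, 0.14),
                         edge_offset_sd_by_session = c(0.02, 0.02, 0.06),
                         gaze_offset_mean = -0.10,
                         fix_dur_shape = 4,
                         fix_dur_rate = 8,
                         jitter_sd = 0.01,
                         explore_center = 0.15,
                         explore_sd = 0.10,
                         explore_dur_shape = 2,
                         explore_dur_rate = 13.3,
                         explore_dur_max_s = 0.3,
                         track_lag_s_by_session = c(0.15, 0.05, 0.05),
                         edge_base = 0.62,
                         edge_level_sd = 0.05,
                         edge_level_values = NULL,
                         edge_step_period_s = 5,
                         edge_wobble_amp = 0.003,
                         edge_wobble_period_s = 7,
                         n_template_points = 30,
                         outlier_frac = 0.3,
                         point_jitter_sd = 0.002,
                         hours_by_session = c(0, 50, 100),
                         perf_initial = 2,
                         perf_asymptote = 9,
                         perf_rate = 0.25,
                         perf_noise_sd = 0.4,
                         percussion_start = 10,
                         percussion_step = 0.55,
                         percussion_noise_sd = 0.5,
                         aptitude_score_gain = 0.8,
                         aptitude_error_gain = 0.8,
                         aptitude_offset_gain = 0.03,
                         latent_coupling = 0.8,
                         missing_rate = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg A `synth_config` object.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  stop_if_not_number(cfg$n_subjects, "n_subjects", lower = 1)
  stop_if_not_number(cfg$video_duration_s, "video_duration_s", lower = 1)
  stop_if_not_number(cfg$sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  stop_if_not_number(cfg$frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  for (p in c("press_response_prob", "outlier_frac", "missing_rate")) {
    stop_if_not_number(cfg[[p]], p, lower = 0, upper = 1)
  }
  stop_if_not_number(cfg$latent_coupling, "latent_coupling",
                     lower = -1, upper = 1)
  bad <- setdiff(names(cfg$phase_weights), ACTION_PHASES)
  if (length(bad) > 0) {
    stop("unknown phase label(s) in phase_weights: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(cfg$phase_weights)) || any(cfg$phase_weights < 0) ||
      sum(cfg$phase_weights) <= 0) {
    stop("phase_weights must be named, non-negative and not all zero",
         call. = FALSE)
  }
  if (!all(names(cfg$phase_weights) %in% names(cfg$phase_mean_len_s))) {
    stop("every weighted phase needs a mean segment length", call. = FALSE)
  }
  if (!is.null(cfg$phase_layout)) {
    if (!all(c("phase", "len_s") %in% names(cfg$phase_layout))) {
      stop("phase_layout needs columns `phase` and `len_s`", call. = FALSE)
    }
    bad <- setdiff(unique(cfg$phase_layout$phase), ACTION_PHASES)
    if (length(bad) > 0) {
      stop("unknown phase label(s) in phase_layout: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (sum(cfg$phase_layout$len_s) != cfg$video_duration_s) {
      stop("phase_layout lengths must sum to video_duration_s", call. = FALSE)
    }
  }
  ns <- length(cfg$sessions)
  if (length(cfg$gaze_cv_by_session) != ns ||
      length(cfg$edge_offset_sd_by_session) != ns ||
      length(cfg$track_lag_s_by_session) != ns ||
      length(cfg$hours_by_session) != ns) {
    stop("per-session parameter vectors must match length(sessions)",
         call. = FALSE)
  }
  if (!(cfg$salient_phase %in% ACTION_PHASES)) {
    stop("salient_phase must be one of the six action phases", call. = FALSE)
  }
  cfg
}

subject_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_subjects))
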