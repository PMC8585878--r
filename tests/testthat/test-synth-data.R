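test_that("a dataset is a pure function of its configuration", {
  cfg <- tiny_cfg()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$phase_track, d2$phase_track)
  expect_identical(d1$presses, d2$presses)
  expect_identical(d1$gaze, d2$gaze)
  expect_identical(d1$performance, d2$performance)
  expect_identical(d1$edge_truth, d2$edge_truth)
})

test_that("phase track has one label per second from the closed vocabulary", {
  cfg <- tiny_cfg(video_duration_s = 1024)
  tr <- generate_phase_track(cfg)
  expect_equal(nrow(tr), 1024)
  expect_true(all(tr$phase %in% ACTION_PHASES))

  only_move <- tiny_cfg(phase_weights = c(core_move = 1),
                        phase_mean_len_s = c(core_move = 5))
  expect_true(all(generate_phase_track(only_move)$phase == "core_move"))

  expect_error(tiny_cfg(phase_weights = c(juggling = 1)), "unknown phase")
  bad_layout <- data.frame(phase = "core_move", len_s = 100)
  expect_error(tiny_cfg(phase_layout = bad_layout), "sum to video_duration_s")
})

test_that("presses land at salient onsets under degenerate parameters", {
  cfg <- tiny_cfg(press_response_prob = 1, press_lag_mean_s = 0,
                  press_lag_sd_s = 0, press_background_rate_hz = 0)
  tr <- generate_phase_track(cfg)
  onsets <- attr(tr, "segments")
  onsets <- onsets$start_s[onsets$phase == "core_move"]
  pr <- generate_presses(cfg, tr)
  for (sess in cfg$sessions) {
    for (s in sprintf("S%02d", 1:5)) {
      lat <- pr$latency_s[pr$subject == s & pr$session == sess]
      expect_equal(sort(lat), sort(onsets))
    }
  }

  none <- tiny_cfg(press_response_prob = 0, press_background_rate_hz = 0)
  expect_equal(nrow(generate_presses(none, tr)), 0)
})

test_that("responders per salient event follow the binomial rate", {
  n_ev <- 250
  p <- 0.6
  cfg <- synth_config(n_subjects = 8, video_duration_s = n_ev * 4,
                      phase_layout = salient_layout(n_ev, on_s = 1, off_s = 3),
                      press_response_prob = p, press_lag_mean_s = 0,
                      press_lag_sd_s = 0, press_background_rate_hz = 0,
                      sessions = "Pre", gaze_cv_by_session = 0.15,
                      edge_offset_sd_by_session = 0.02,
                      track_lag_s_by_session = 0.1, hours_by_session = 0,
                      seed = 7)
  tr <- generate_phase_track(cfg)
  pr <- generate_presses(cfg, tr)
  onsets <- seq(0, by = 4, length.out = n_ev)
  responders <- vapply(onsets, function(t0) {
    length(unique(pr$subject[abs(pr$latency_s - t0) < 0.5]))
  }, numeric(1))
  se <- sqrt(8 * p * (1 - p)) / sqrt(n_ev)
  expect_lt(abs(mean(responders) - 8 * p), 3 * se)
})

test_that("noiseless gaze tracks the working edge exactly during fixations", {
  cfg <- tiny_cfg(n_subjects = 2, jitter_sd = 0,
                  gaze_offset_mean = 0, aptitude_offset_gain = 0,
                  edge_offset_sd_by_session = rep(0, 3),
                  gaze_cv_by_session = rep(0.01, 3),  # below floor: no glances
                  track_lag_s_by_session = rep(0, 3),
                  edge_wobble_amp = 0)
  ds <- generate_dataset(cfg)
  g <- ds$gaze[ds$gaze$session == "Pre" & ds$gaze$subject == "S01", ]
  # compare against the step level active at each gaze sample
  fi <- pmax(findInterval(g$t_s, ds$edge_truth$t_s), 1)
  expect_lt(max(abs(g$x - ds$edge_truth$edge_x[fi])), 1e-10)
})

test_that("within-fixation jitter realizes its configured scale", {
  cfg <- synth_config(n_subjects = 1, video_duration_s = 180,
                      sessions = "Pre", gaze_cv_by_session = 0.01,
                      edge_offset_sd_by_session = 0,
                      track_lag_s_by_session = 0, hours_by_session = 0,
                      edge_level_values = 0.6, edge_wobble_amp = 0,
                      gaze_offset_mean = 0, aptitude_offset_gain = 0,
                      jitter_sd = 0.05, seed = 11)
  ds <- generate_dataset(cfg)
  s <- sd(ds$gaze$x)
  expect_lt(abs(s - 0.05) / 0.05, 0.1)
})

test_that("measured gaze CV is ordered as configured across sessions", {
  cfg <- synth_config(n_subjects = 20, video_duration_s = 256,
                      gaze_cv_by_session = c(0.3, 0.15, 0.15), seed = 5)
  ds <- generate_dataset(cfg)
  cv_sess <- vapply(cfg$sessions, function(sess) {
    g <- ds$gaze[ds$gaze$session == sess, ]
    mean(vapply(unique(g$subject), function(s) {
      gaze_cv(g[g$subject == s, ], 0, 256)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cv_sess["Pre"], cv_sess["Post1"])
  expect_gt(cv_sess["Pre"], cv_sess["Post2"])
})

test_that("performance follows a power curve with planted latent coupling", {
  flat <- tiny_cfg(perf_rate = 0, perf_noise_sd = 0)
  perf <- generate_performance(flat)
  for (s in unique(perf$subject)) {
    expect_equal(var(perf$handaxe_score[perf$subject == s]), 0)
  }

  indep <- synth_config(n_subjects = 200, latent_coupling = 0, seed = 3)
  lat0 <- knapgaze:::generate_latent(indep)
  expect_lt(abs(cor(lat0$aptitude, lat0$gaze_factor)), 0.2)

  coupled <- synth_config(n_subjects = 200, latent_coupling = 0.8, seed = 3)
  lat8 <- knapgaze:::generate_latent(coupled)
  r <- cor(lat8$aptitude, lat8$gaze_factor)
  expect_gt(r, 0.7)
  expect_lt(r, 0.9)

  # scores rise toward the asymptote with practice
  perf2 <- generate_performance(tiny_cfg(perf_noise_sd = 0,
                                         aptitude_score_gain = 0))
  by_sess <- tapply(perf2$handaxe_score, perf2$session, mean)
  expect_gt(by_sess[["Post1"]], by_sess[["Pre"]])
  expect_gt(by_sess[["Post2"]], by_sess[["Post1"]])
})

test_that("gaze coordinates stay in the unit square and presses in the video", {
  ds <- generate_dataset(tiny_cfg())
  expect_true(all(ds$gaze$x >= 0 & ds$gaze$x <= 1))
  expect_true(all(ds$gaze$y >= 0 & ds$gaze$y <= 1))
  expect_true(all(ds$presses$latency_s >= 0 &
                    ds$presses$latency_s <= 128))
})

test_that("written CSV files round-trip through the readers", {
  ds <- generate_dataset(tiny_cfg(n_subjects = 3, video_duration_s = 64))
  dir <- withr::local_tempdir()
  write_synth_dataset(ds, dir)
  gz <- read.csv(file.path(dir, "gaze.csv"))
  expect_equal(nrow(gz), nrow(ds$gaze))
  expect_equal(validate_inputs(dir)$severity, character(0))
})
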