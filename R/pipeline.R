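#' Configuration of a full pipeline run
#'
#' @param synth A [synth_config()] to generate inputs, or NULL when reading
#'   CSV inputs from `input_dir`.
#' @param input_dir Directory with `gaze.csv`, `presses.csv`, `phases.csv`,
#'   `performance.csv`, `template.csv` and either `frame_points.csv` or
#'   `edge.csv` (formats of [write_synth_dataset()]).
#' @param window_s,slide_s Salience window length and slide (s).
#' @param percentile Probability-threshold percentile (default 90).
#' @param target_phase Phase of interest (default `"core_move"`).
#' @param n_windows Keep at most this many merged windows, by descending
#'   probability with earlier windows first on ties (default 40, the
#'   bookkeeping used throughout the analysis).
#' @param k Cluster count; NULL for automatic selection per window.
#' @param ransac_n_iter,ransac_tol,ransac_floor RANSAC parameters.
#' @param n_boot Bootstrap resamples for shift functions.
#' @param alpha Significance level.
#' @param shift_measures Measures to pass through the shift-function stage.
#' @param seed Root seed for every stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       input_dir = NULL,
                       window_s = 10, slide_s = 5,
                       percentile = 90,
                       target_phase = "core_move",
                       n_windows = 40,
                       k = NULL,
                       ransac_n_iter = 500,
                       ransac_tol = 0.005,
                       ransac_floor = 0.3,
                       n_boot = 2000,
                       alpha = 0.05,
                       shift_measures = c(GAZE_VARS,
                                          "handaxe_score",
                                          "percussion_error"),
                       seed = 1) {
  if (is.null(synth) && is.null(input_dir)) {
    stop("either `synth` or `input_dir` must be given", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [run_config()] arguments; a `synth:` mapping maps
#' to [synth_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  do.call(run_config, y)
}

read_pipeline_inputs <- function(input_dir) {
  need <- c("gaze.csv", "presses.csv", "phases.csv", "performance.csv",
            "template.csv")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ds <- list(
    gaze = read.csv(file.path(input_dir, "gaze.csv")),
    presses = read.csv(file.path(input_dir, "presses.csv")),
    phase_track = read.csv(file.path(input_dir, "phases.csv")),
    performance = read.csv(file.path(input_dir, "performance.csv")),
    template = read.csv(file.path(input_dir, "template.csv")),
    frame_points = NULL, edge_truth = NULL, config = NULL
  )
  fp <- file.path(input_dir, "frame_points.csv")
  if (file.exists(fp)) ds$frame_points <- read.csv(fp)
  ep <- file.path(input_dir, "edge.csv")
  if (file.exists(ep)) ds$edge_truth <- read.csv(ep)
  if (!is.null(ds$frame_points) && !("t_s" %in% names(ds$frame_points))) {
    if (is.null(ds$edge_truth)) {
      stop("frame_points.csv lacks t_s and no edge.csv maps frames to time",
           call. = FALSE)
    }
    ds$frame_points$t_s <- ds$edge_truth$t_s[
      match(ds$frame_points$frame, ds$edge_truth$frame)]
  }
  ds
}

# frame indices (0-based) covering [start, end) for a set of merged windows
window_frames <- function(merged, fps) {
  idx <- unlist(lapply(seq_len(nrow(merged)), function(i) {
    seq(floor(merged$start_s[i] * fps),
        ceiling(merged$end_s[i] * fps) - 1L)
  }))
  sort(unique(idx))
}

#' Run the full perceptuomotor analysis pipeline
#'
#' Executes, in order: press-matrix construction (sessions pooled),
#' salience series and window selection; per-session Ward time clustering
#' of every retained window; working-edge tracking by RANSAC and
#' edge-referenced spatial dispersion; per-subject gaze CV; within-condition
#' subject permutation and session means; decile shift functions
#' (`Shift1` = Post1 vs Pre, `Shift2` = Post2 vs Post1) and effect sizes;
#' and per-session canonical correlation between the performance variate
#' (learning slope, handaxe score, percussion error) and the gaze variate
#' (gaze CV, mean distance, edge variability). The whole run is a pure
#' function of the configuration (seed included).
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `results_bundle`: list of tables
#'   (`salience_series`, `selected_windows`, `merged_windows`,
#'   `cluster_summary`, `central_objects`, `edge_trajectory`,
#'   `gaze_params`, `session_means`, `perceptuomotor`, `shift_functions`,
#'   `effect_sizes`, `cca_modes`, `cca_weights`) plus a `manifest`.
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  notes <- character(0)
  say <- function(...) if (!quiet) message(sprintf(...))
  note_handler <- function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = note_handler),
             error = function(e) {
               stop(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE)
             })
  }

  # --- inputs -------------------------------------------------------------
  ds <- stage("inputs", {
    if (!is.null(cfg$synth)) generate_dataset(cfg$synth)
    else read_pipeline_inputs(cfg$input_dir)
  })
  sessions <- if (!is.null(ds$config)) ds$config$sessions else
    unique(as.character(ds$gaze$session))
  duration_s <- nrow(ds$phase_track)
  fs <- if (!is.null(ds$config)) ds$config$sample_rate_hz else
    round(1 / min(diff(sort(unique(ds$gaze$t_s[ds$gaze$subject ==
                                                 ds$gaze$subject[1]])))))
  say("inputs ready: %d sessions, %d s video", length(sessions), duration_s)

  # --- salience (sessions pooled into one subject|session matrix) ---------
  sal <- stage("salience", {
    pooled <- ds$presses
    pooled$subject <- paste(pooled$subject, pooled$session, sep = "|")
    all_ids <- as.vector(outer(unique(as.character(ds$gaze$subject)),
                               sessions, paste, sep = "|"))
    pm <- build_press_matrix(pooled, duration_s, subjects = sort(all_ids))
    series <- salience_series(pm, cfg$window_s, cfg$slide_s)
    sel <- select_windows(series, ds$phase_track, cfg$percentile,
                          cfg$target_phase)
    list(pm = pm, series = series, sel = sel)
  })
  merged <- sal$sel$merged
  if (nrow(merged) == 0) {
    stop("pipeline stage 'salience' failed: no meaningful windows retained",
         call. = FALSE)
  }
  if (!is.null(cfg$n_windows) && nrow(merged) > cfg$n_windows) {
    ord <- order(-merged$probability, merged$start_s)
    merged <- merged[sort(ord[seq_len(cfg$n_windows)]), ]
    rownames(merged) <- NULL
  }
  merged$window <- seq_len(nrow(merged))
  say("retained %d merged windows (threshold %.3f)", nrow(merged),
      sal$sel$threshold)

  # --- edge tracking (one video, shared across sessions) ------------------
  trajectory <- stage("edge_tracking", {
    if (!is.null(ds$frame_points) || !is.null(ds$config)) {
      fps <- if (!is.null(ds$config)) ds$config$frame_rate_hz else
        round(1 / min(diff(sort(unique(ds$frame_points$t_s)))))
      frames <- if (!is.null(ds$frame_points)) {
        idx <- window_frames(merged, fps)
        ds$frame_points[ds$frame_points$frame %in% idx, ]
      } else {
        generate_frame_points(ds$config, ds$edge_truth, ds$template,
                              frames = window_frames(merged, fps))
      }
      track_edge(ds$template, frames, n_iter = cfg$ransac_n_iter,
                 inlier_tol = cfg$ransac_tol,
                 min_inlier_frac = cfg$ransac_floor,
                 seed = derive_seed(cfg$seed, 11L))
    } else if (!is.null(ds$edge_truth)) {
      # externally supplied edge trajectory: use as-is
      out <- data.frame(frame = ds$edge_truth$frame,
                        t_s = ds$edge_truth$t_s,
                        tx = NA_real_, ty = NA_real_,
                        edge_x = ds$edge_truth$edge_x,
                        inlier_frac = NA_real_, ok = TRUE,
                        interpolated = FALSE)
      class(out) <- c("edge_trajectory", class(out))
      out
    } else {
      stop("no frame points and no edge trajectory available")
    }
  })

  # --- clustering + spatial dispersion + CV per session x window ----------
  cluster_summary <- list()
  central_rows <- list()
  cv_rows <- list()
  for (sess in sessions) {
    gz <- ds$gaze[ds$gaze$session == sess, ]
    for (w in seq_len(nrow(merged))) {
      res <- stage(sprintf("clustering[%s w%d]", sess, w), {
        m <- extract_window_matrix(gz, merged$start_s[w], merged$end_s[w],
                                   sample_rate_hz = fs)
        ward_cluster(m, k = cfg$k)
      })
      cluster_summary[[length(cluster_summary) + 1L]] <- data.frame(
        session = sess, window = w, k = res$k,
        within_class_pct = res$within_class_pct,
        between_class_pct = res$between_class_pct,
        dissimilarity = res$dissimilarity)
      co <- res$central_objects
      central_rows[[length(central_rows) + 1L]] <- data.frame(
        session = sess, window = w,
        cluster = rep(co$cluster, each = ncol(co$gaze)),
        t_centroid = rep(co$t_s, each = ncol(co$gaze)),
        subject = rep(colnames(co$gaze), length(co$cluster)),
        gaze_x = as.numeric(t(co$gaze)))
      for (s in unique(as.character(gz$subject))) {
        cv_rows[[length(cv_rows) + 1L]] <- data.frame(
          session = sess, window = w, subject = s,
          gaze_cv = stage("gaze_cv", gaze_cv(gz[gz$subject == s, ],
                                             merged$start_s[w],
                                             merged$end_s[w])))
      }
    }
  }
  cluster_summary <- do.call(rbind, cluster_summary)
  central_objects_tbl <- do.call(rbind, central_rows)
  cv_tbl <- do.call(rbind, cv_rows)
  say("clustered %d session-windows", nrow(cluster_summary))

  spatial <- stage("spatial_dispersion", {
    rec <- centroid_distances(central_objects_tbl, trajectory)
    spatial_dispersion(rec)
  })

  gaze_params <- stage("gaze_params", {
    gp <- merge(cv_tbl, spatial,
                by = c("subject", "session", "window"), all.x = TRUE)
    gp <- gp[order(gp$session, gp$window, gp$subject),
             c("subject", "session", "window", "gaze_cv",
               "mean_distance", "edge_variability")]
    rownames(gp) <- NULL
    gp
  })

  # --- permutation + session means ---------------------------------------
  perm <- stage("permutation", {
    permute_within_condition(gaze_params, measures = GAZE_VARS,
                             seed = derive_seed(cfg$seed, 12L))
  })
  session_means <- perm$session_means

  # --- perceptuomotor table ----------------------------------------------
  perceptuomotor <- stage("perceptuomotor", {
    slopes <- learning_slopes(ds$performance)
    pm <- merge(session_means, ds$performance,
                by = c("subject", "session"))
    pm <- merge(pm, slopes[c("subject", "learning_slope")], by = "subject")
    pm <- pm[order(match(pm$session, sessions), pm$subject),
             c("subject", "session", "hours", GAZE_VARS,
               "learning_slope", "handaxe_score", "percussion_error")]
    rownames(pm) <- NULL
    pm
  })

  # --- shift functions + effect sizes ------------------------------------
  shifts <- list()
  effects <- list()
  pairs <- list(Shift1 = c(sessions[1], sessions[2]),
                Shift2 = c(sessions[2], sessions[3]))
  for (meas in cfg$shift_measures) {
    vals <- split(perceptuomotor[[meas]], perceptuomotor$session)
    for (sh in names(pairs)) {
      pr <- pairs[[sh]]
      sf <- stage(sprintf("shift[%s %s]", meas, sh), {
        shift_function(vals[[pr[1]]], vals[[pr[2]]], n_boot = cfg$n_boot,
                       alpha = cfg$alpha,
                       seed = derive_seed(cfg$seed,
                                          13L + match(meas, cfg$shift_measures) * 10L +
                                            match(sh, names(pairs))))
      })
      sf$measure <- meas
      sf$comparison <- sprintf("%s (%s - %s)", sh, pr[2], pr[1])
      shifts[[length(shifts) + 1L]] <- as.data.frame(sf)
    }
    es <- stage(sprintf("effects[%s]", meas), {
      om <- eta_sq_epsilon_sq(perceptuomotor[[meas]],
                              perceptuomotor$session)
      gs <- vapply(names(pairs), function(sh) {
        pr <- pairs[[sh]]
        hedges_g(vals[[pr[2]]], vals[[pr[1]]])
      }, numeric(1))
      data.frame(measure = meas, eta_squared = om$eta_squared,
                 epsilon_squared = om$epsilon_squared,
                 hedges_g_shift1 = gs[["Shift1"]],
                 hedges_g_shift2 = gs[["Shift2"]])
    })
    effects[[length(effects) + 1L]] <- es
  }
  shift_functions <- do.call(rbind, shifts)
  effect_sizes <- do.call(rbind, effects)

  # --- canonical correlation per session ----------------------------------
  cca_results <- lapply(sessions, function(sess) {
    d <- perceptuomotor[perceptuomotor$session == sess, ]
    Xa <- as.matrix(d[PERFORMANCE_VARS])
    Xb <- as.matrix(d[GAZE_VARS])
    rownames(Xa) <- rownames(Xb) <- d$subject
    stage(sprintf("cca[%s]", sess), cca(Xa, Xb, session = sess))
  })
  cca_weights <- stage("cca_report", {
    mode_report(cca_results, variate_names = c("performance", "gaze"))
  })
  cca_modes <- unique(cca_weights[c("session", "mode",
                                    "canonical_correlation", "r_squared")])
  rownames(cca_modes) <- NULL

  # --- manifest -----------------------------------------------------------
  tables <- list(
    salience_series = sal$series,
    selected_windows = sal$sel$windows,
    merged_windows = merged,
    cluster_summary = cluster_summary,
    central_objects = central_objects_tbl,
    edge_trajectory = as.data.frame(trajectory),
    gaze_params = gaze_params,
    session_means = session_means,
    perceptuomotor = perceptuomotor,
    shift_functions = shift_functions,
    effect_sizes = effect_sizes,
    cca_modes = cca_modes,
    cca_weights = cca_weights
  )
  manifest <- list(
    config = serialize_config(cfg),
    config_hash = config_hash(cfg),
    threshold = sal$sel$threshold,
    n_windows_retained = nrow(merged),
    sessions = sessions,
    row_counts = lapply(tables, nrow),
    warnings = notes,
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(c(tables, list(manifest = manifest)), class = "results_bundle")
}

serialize_config <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, "synth_config") || inherits(x, "run_config")) {
      lapply(unclass(x), strip)
    } else if (is.data.frame(x)) as.list(x) else x
  }
  strip(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(serialize_config(cfg), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a results bundle to a directory of CSV files plus a JSON manifest
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in setdiff(names(bundle), "manifest")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  # timing is run-specific, not part of the reproducible payload
  man <- bundle$manifest
  man$elapsed_s <- NULL
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, mp))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("perceptuomotor results bundle\n")
  for (nm in setdiff(names(x), "manifest")) {
    cat(sprintf("  %-18s %6d rows\n", nm, nrow(x[[nm]])))
  }
  cat(sprintf("  windows retained: %d, config %s\n",
              x$manifest$n_windows_retained, x$manifest$config_hash))
  invisible(x)
}

#' Validate pipeline input files
#'
#' Schema and consistency checks over the CSV interchange files: required
#' columns, coordinate and probability ranges, strictly increasing
#' timestamps per subject and session, latencies within the video, and
#' subject/session cross-references between files. Never raises; every
#' finding is returned with a severity level.
#'
#' @param input_dir Directory holding the CSV files (see
#'   [write_synth_dataset()] for formats).
#' @return Data.frame (`severity`, `file`, `message`); zero rows mean a
#'   fully clean bundle.
#' @export
validate_inputs <- function(input_dir) {
  findings <- list()
  add <- function(severity, file, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, file = file, message = message)
  }
  get <- function(name, cols) {
    p <- file.path(input_dir, name)
    if (!file.exists(p)) {
      add("error", name, "file missing")
      return(NULL)
    }
    d <- tryCatch(read.csv(p), error = function(e) {
      add("error", name, paste("unreadable:", conditionMessage(e)))
      NULL
    })
    if (!is.null(d)) {
      missing <- setdiff(cols, names(d))
      if (length(missing) > 0) {
        add("error", name,
            paste("missing column(s):", paste(missing, collapse = ", ")))
        return(NULL)
      }
    }
    d
  }
  gaze <- get("gaze.csv", c("subject", "session", "t_s", "x", "y"))
  presses <- get("presses.csv", c("subject", "session", "latency_s"))
  phases <- get("phases.csv", c("second", "phase"))
  perf <- get("performance.csv",
              c("subject", "session", "hours", "handaxe_score",
                "percussion_error"))
  duration <- if (!is.null(phases)) nrow(phases) else NA_real_
  if (!is.null(phases)) {
    bad <- setdiff(unique(as.character(phases$phase)), ACTION_PHASES)
    if (length(bad) > 0) {
      add("error", "phases.csv",
          paste("unknown phase label(s):", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(gaze)) {
    v <- if ("valid" %in% names(gaze)) as.logical(gaze$valid) else TRUE
    if (any((gaze$x < 0 | gaze$x > 1 | gaze$y < 0 | gaze$y > 1) & v,
            na.rm = TRUE)) {
      add("error", "gaze.csv", "coordinates outside [0, 1] on valid samples")
    }
    key <- paste(gaze$subject, gaze$session)
    mono <- vapply(split(gaze$t_s, key),
                   function(t) all(diff(t) > 0), logical(1))
    if (!all(mono)) {
      add("error", "gaze.csv",
          paste("non-increasing timestamps for:",
                paste(names(mono)[!mono], collapse = ", ")))
    }
  }
  if (!is.null(presses) && !is.na(duration)) {
    if (any(presses$latency_s < 0 | presses$latency_s > duration)) {
      add("error", "presses.csv", "latency outside the video duration")
    }
  }
  if (!is.null(gaze) && !is.null(presses)) {
    only_g <- setdiff(unique(gaze$subject), unique(presses$subject))
    only_p <- setdiff(unique(presses$subject), unique(gaze$subject))
    if (length(only_g) > 0) {
      add("warning", "presses.csv",
          paste("subject(s) in gaze but not in presses:",
                paste(only_g, collapse = ", ")))
    }
    if (length(only_p) > 0) {
      add("warning", "gaze.csv",
          paste("subject(s) in presses but not in gaze:",
                paste(only_p, collapse = ", ")))
    }
  }
  if (!is.null(gaze) && !is.null(perf)) {
    miss <- setdiff(unique(gaze$subject), unique(perf$subject))
    if (length(miss) > 0) {
      add("warning", "performance.csv",
          paste("subject(s) without performance rows:",
                paste(miss, collapse = ", ")))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(severity = character(0), file = character(0),
                      message = character(0)))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}
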