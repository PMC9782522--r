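empty_matches <- function() {
  data.frame(prev_idx = integer(), cur_idx = integer(), species = character(),
             dist = numeric(), dx_px = numeric(), dy_px = numeric())
}

#' Run the spray control loop over a detection stream
#'
#' The per-frame loop of one scalable unit: threshold detections at the
#' operating confidence, associate with the previous frame, update the
#' velocity estimate, append spray schedules for weed boxes, then poll the
#' queue once per frame (the poll period equals the frame period) and clear
#' schedules covered by any fired footprint.
#'
#' In simulation the frame-centre ground position comes from the true
#' trajectory (`truth_x`); in replay it is integrated from the velocity
#' estimate starting at `x0`, so only control-visible quantities
#' (trigger times, valve count, clearing) are exactly reproducible.
#'
#' @param stream a `detection_stream` (simulated or read from a log).
#' @param cam a `camera_model`.
#' @param nozzle a `nozzle_spec`.
#' @param truth_x numeric vector of true frame-centre positions (one per
#'   frame), or `NULL` to integrate the velocity estimate.
#' @param x0 starting frame-centre position used when integrating.
#' @param conf_thr detection confidence threshold (default 0.5).
#' @param gate_px association gate, pixels.
#' @param k velocity rolling-median window, frames.
#' @param guard_covered suppress new schedules for ground already wetted by
#'   the most recent fired footprint (feedback filter; default `TRUE`).
#' @param y_center across-travel footprint centre (row centreline in
#'   global coordinates), metres.
#' @return list: `events` (data.frame of fired sprays), `queue` (final
#'   `spray_queue`), `velocity_log` (data.frame: frame_index, t, v,
#'   n_tracks, valid).
#' @export
run_stream <- function(stream, cam, nozzle, truth_x = NULL, x0 = 0,
                       conf_thr = 0.5, gate_px = 120, k = 5L,
                       guard_covered = TRUE, y_center = 0) {
  dt <- 1 / cam$fps
  gsd_x <- cam$gsd[["x"]]
  state <- velocity_tracker(k)
  queue <- spray_queue()
  events <- list()
  last_event <- NULL
  prev <- NULL
  x_hat <- x0
  vlog <- vector("list", length(stream))
  for (i in seq_along(stream)) {
    f <- stream[[i]]
    fb <- f$boxes[f$boxes$confidence >= conf_thr, , drop = FALSE]
    fthr <- frame_detections(f$frame_index, f$t, fb)
    m <- if (is.null(prev)) empty_matches() else associate(prev, fthr, gate_px)
    r <- estimate_velocity(m, dt, gsd_x, state, t = f$t)
    state <- r$state
    vel <- r$estimate
    v_now <- if (!is.na(state$last)) state$last else 0
    if (is.null(truth_x)) {
      if (i > 1L) x_hat <- x_hat + v_now * dt
      x_i <- x_hat
    } else {
      x_i <- truth_x[i]
    }
    wb <- fb[fb$species == "weed", , drop = FALSE]
    queue <- schedule(queue, wb, vel, nozzle, cam, f$t, x_i,
                      source_frame = f$frame_index,
                      guard = if (guard_covered) last_event else NULL)
    pr <- poll(queue, f$t, nozzle, v_now, x_i, y_center)
    queue <- pr$queue
    if (!is.null(pr$event)) {
      cc <- clear_covered(queue, pr$event)
      queue <- cc$queue
      pr$event$n_cleared <- cc$n_cleared
      events[[length(events) + 1L]] <- pr$event
      last_event <- pr$event
    }
    vlog[[i]] <- data.frame(frame_index = f$frame_index, t = f$t,
                            v = if (is.na(vel$v)) NA_real_ else vel$v,
                            n_tracks = vel$n_tracks, valid = vel$valid)
    prev <- fthr
  }
  ev <- if (length(events)) do.call(rbind, events) else
    utils::head(poll(spray_queue(), 0, nozzle, 0, 0)$event, 0)
  list(events = ev, queue = queue, velocity_log = do.call(rbind, vlog))
}

#' Default simulation configuration
#'
#' Mirrors the replica field-trial conditions: three 0.5 m x 10 m rows at
#' 6.6 / 17.8 / 11.8 weeds/m2 with exact populations (33/89/59 weeds),
#' 39.5 soybeans/m2, a 1280x720 @ 19 fps camera over a 0.95 m x 0.53 m
#' ground window, the 1.6 L/min / 0.2 s / 0.45 m / 1.08 m nozzle, detector
#' noise at the 68% per-frame recall operating point, and per-frame ground
#' speed drawn uniformly in 0.53-0.83 m/s; 30 weed and 30 soybean samples,
#' 3 trials.
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    rows = list(
      list(length = 10, width = 0.5, weed_density = 6.6),
      list(length = 10, width = 0.5, weed_density = 17.8),
      list(length = 10, width = 0.5, weed_density = 11.8)),
    soy_density = 39.5,
    emergence = 1,
    exact_counts = TRUE,
    camera = list(resolution = c(1280L, 720L), fps = 19,
                  ground_window = c(0.95, 0.53)),
    nozzle = list(flow_rate_lpm = 1.6, open_time_s = 0.2, height_m = 0.45,
                  pattern_width_m = 1.08, offset_m = 0.30),
    noise = list(miss = c(weed = 0.32, soybean = 0.32), misclass = 0,
                 clutter_rate = 0.2, center_jitter_px = 3,
                 size_jitter = 0.05),
    trajectory = list(v = 0.69, v_range = c(0.53, 0.83)),
    n_trials = 3L,
    n_weed_samples = 30L,
    n_soy_samples = 30L,
    adjacency_radius = 0.15,
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

#' Load and validate a run configuration from YAML or JSON
#'
#' Unknown fields are rejected with their path; missing fields take the
#' [default_config()] values.
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(default_config())
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_param("unknown config field(s): ",
                              paste(bad, collapse = ", "))
  if (!is.null(raw$noise$miss)) raw$noise$miss <- unlist(raw$noise$miss)
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop_param("config field '", field, "': ", msg)
  }
  chk(length(cfg$rows) >= 1, "rows", "at least one row required")
  for (i in seq_along(cfg$rows)) {
    r <- cfg$rows[[i]]
    chk(r$length > 0 && r$width > 0, paste0("rows[", i, "]"),
        "length and width must be > 0")
    chk(r$weed_density >= 0, paste0("rows[", i, "].weed_density"), ">= 0")
  }
  chk(cfg$soy_density >= 0, "soy_density", ">= 0")
  chk(cfg$camera$fps > 0, "camera.fps", "> 0")
  chk(cfg$n_trials >= 0, "n_trials", ">= 0")
  chk(is.numeric(cfg$seed), "seed", "mandatory integer seed")
  if (!is.null(cfg$trajectory$v_range)) {
    chk(cfg$trajectory$v_range[1] > 0, "trajectory.v_range", "speeds must be > 0")
  } else {
    chk(cfg$trajectory$v > 0, "trajectory.v", "> 0")
  }
  cfg
}

config_objects <- function(cfg) {
  list(
    specs = lapply(cfg$rows, function(r) {
      row_spec(length = r$length, width = r$width,
               weed_density = r$weed_density,
               soy_density = cfg$soy_density, emergence = cfg$emergence)
    }),
    cam = do.call(camera_model, cfg$camera),
    nozzle = do.call(nozzle_spec, cfg$nozzle),
    noise = do.call(noise_model, cfg$noise))
}

#' Run a full simulated spraying experiment
#'
#' Generates the field once (the physical rows are fixed across trials),
#' marks the weed/soybean samples, and runs `n_trials` independent passes:
#' each trial draws its own trajectory and detection noise, runs the
#' control loop per row (one scalable unit each), and is scored against
#' the ground truth. The report mirrors the field-trial tables: per-trial
#' confusion counts and targeting metrics, metrics of the averaged counts
#' alongside the mean of per-trial metrics (the two differ in general),
#' and per-row plus pooled volume accounting.
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @param out_dir optional directory; when given, detection, velocity and
#'   spray-event logs plus `report.json` are written there.
#' @param noiseless_override replace the configured noise model with
#'   [noiseless()] (acceptance-style runs).
#' @return A `run_report` list.
#' @export
run_simulation <- function(config, out_dir = NULL, noiseless_override = FALSE) {
  cfg <- validate_config(config)
  ob <- config_objects(cfg)
  if (noiseless_override) ob$noise <- noiseless()
  if (cfg$n_trials == 0L) {
    rep0 <- structure(list(config = unclass(cfg), seed = cfg$seed, trials = list(),
                           counts_mean = NULL, metrics_of_mean_counts = NULL,
                           metrics_mean = NULL, volume = NULL),
                      class = "run_report")
    return(rep0)
  }
  plot <- generate_field(ob$specs, seed = cfg$seed,
                         exact_counts = isTRUE(cfg$exact_counts))
  plot <- mark_samples(plot, cfg$n_weed_samples, cfg$n_soy_samples,
                       cfg$adjacency_radius, seed = cfg$seed)
  fp_static <- footprint(ob$nozzle, 0)[["length"]]
  v_low <- if (!is.null(cfg$trajectory$v_range)) cfg$trajectory$v_range[1] else
    cfg$trajectory$v
  x0 <- cfg$trajectory$x0 %||% -(ob$cam$ground_window[1] / 2 + ob$nozzle$offset_m)
  row_w <- vapply(ob$specs, function(s) s$width, numeric(1))
  y_centers <- c(0, cumsum(row_w))[seq_along(row_w)] + row_w / 2
  trials <- vector("list", cfg$n_trials)
  for (tr in seq_len(cfg$n_trials)) {
    trial_seed <- derive_seed(cfg$seed, paste0("trial", tr))
    all_events <- list(); valve <- integer(length(ob$specs))
    vlogs <- list(); streams <- list(); durations <- numeric(length(ob$specs))
    for (r in seq_along(ob$specs)) {
      L <- ob$specs[[r]]$length
      duration <- (L + ob$nozzle$offset_m + fp_static / 2 - x0 + 0.1) / v_low
      traj <- if (!is.null(cfg$trajectory$v_range)) {
        make_trajectory(duration, ob$cam$fps, v_range = cfg$trajectory$v_range,
                        x0 = x0, seed = derive_seed(trial_seed, paste0("traj", r)))
      } else {
        make_trajectory(duration, ob$cam$fps, v = cfg$trajectory$v, x0 = x0)
      }
      st <- simulate_stream(plot, ob$cam, traj, ob$noise,
                            seed = derive_seed(trial_seed, paste0("row", r)),
                            row = r)
      res <- run_stream(st, ob$cam, ob$nozzle, truth_x = traj$x, x0 = x0,
                        y_center = y_centers[r])
      if (nrow(res$events)) res$events$row <- r
      all_events[[r]] <- res$events
      valve[r] <- nrow(res$events)
      vlogs[[r]] <- cbind(row = r, res$velocity_log)
      streams[[r]] <- st
      durations[r] <- duration
    }
    events <- do.call(rbind, all_events)
    counts <- classify_outcomes(plot, events)
    trials[[tr]] <- list(events = events, valve_per_row = valve,
                         counts = counts, metrics = targeting_metrics(counts),
                         velocity_log = do.call(rbind, vlogs),
                         streams = streams, durations = durations)
  }
  report <- build_report(cfg, ob, plot, trials)
  if (!is.null(out_dir)) write_run_outputs(report, trials, out_dir)
  report
}

build_report <- function(cfg, ob, plot, trials) {
  cmean <- function(f) mean(vapply(trials, function(tr) tr$counts[[f]], numeric(1)))
  counts_mean <- targeting_counts(cmean("TP"), cmean("TN"), cmean("FP"),
                                  cmean("FN"), cmean("n_soy_without_weed"))
  mm <- function(f) mean(vapply(trials, function(tr) tr$metrics[[f]], numeric(1)))
  valve_mat <- do.call(rbind, lapply(trials, function(tr) tr$valve_per_row))
  n_valve_row <- colMeans(valve_mat)
  t_trials <- trials[[1]]$durations
  vol_rows <- lapply(seq_along(n_valve_row), function(r) {
    volume_metrics(n_valve_row[r], ob$nozzle, t_trials[r])
  })
  vol_all <- volume_metrics(sum(n_valve_row), ob$nozzle, mean(t_trials),
                            n_rows = length(n_valve_row))
  weed_pop <- vapply(seq_along(ob$specs), function(r) {
    sum(plot$plants$species == "weed" & plot$plants$row == r)
  }, numeric(1))
  structure(list(
    config = unclass(cfg), seed = cfg$seed,
    weed_population = weed_pop,
    trials = lapply(trials, function(tr) {
      list(counts = tr$counts[c("TP", "TN", "FP", "FN", "n_soy_without_weed")],
           metrics = unclass(tr$metrics), valve_per_row = tr$valve_per_row)
    }),
    counts_mean = unclass(counts_mean)[c("TP", "TN", "FP", "FN",
                                         "n_soy_without_weed")],
    metrics_of_mean_counts = unclass(targeting_metrics(counts_mean)),
    metrics_mean = list(Ps = mm("Ps"), Rs = mm("Rs"), WS = mm("WS"),
                        NT = mm("NT")),
    volume = list(per_row = lapply(vol_rows, unclass),
                  all = unclass(vol_all))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$trials), " trial(s), seed ", x$seed, "\n", sep = "")
  if (length(x$trials) == 0L) return(invisible(x))
  cat("weed population per row:", paste(x$weed_population, collapse = "/"), "\n")
  for (i in seq_along(x$trials)) {
    tr <- x$trials[[i]]
    cat(sprintf("trial %d: TP=%d TN=%d FP=%d FN=%d  valve=%s\n", i,
                tr$counts$TP, tr$counts$TN, tr$counts$FP, tr$counts$FN,
                paste(tr$valve_per_row, collapse = "/")))
  }
  m <- x$metrics_of_mean_counts
  f <- function(v) if (is.na(v)) "undef" else sprintf("%.2f", v)
  cat("metrics of averaged counts: Ps=", f(m$Ps), " Rs=", f(m$Rs),
      " WS=", f(m$WS), " NT=", f(m$NT), " (%)\n", sep = "")
  cat(sprintf("volume (all rows): Q_var=%.3f L  Q_uni=%.3f L  SVR=%.2f%%\n",
              x$volume$all$q_variable, x$volume$all$q_uniform,
              x$volume$all$svr))
  invisible(x)
}

write_run_outputs <- function(report, trials, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (tr in seq_along(trials)) {
    tdir <- file.path(out_dir, sprintf("trial%02d", tr))
    dir.create(tdir, showWarnings = FALSE)
    for (r in seq_along(trials[[tr]]$streams)) {
      write_detection_log(trials[[tr]]$streams[[r]],
                          file.path(tdir, sprintf("detections_row%d.csv", r)))
    }
    write_velocity_log(trials[[tr]]$velocity_log,
                       file.path(tdir, "velocity.csv"))
    write_event_log(trials[[tr]]$events, file.path(tdir, "events.csv"))
  }
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Write trial-table CSV summaries of a run report
#'
#' Two files mirroring the field-trial report layout: `<stem>_targeting.csv`
#' (one row per trial plus the average row: TP, TN, FP, FN, Ns_wow, Ps, Rs,
#' WS, NT) and `<stem>_volume.csv` (one row per field row plus "all":
#' weed population, mean valve count, valve/weed ratio, Q_variable, SVR).
#'
#' @param report a `run_report` from [run_simulation()].
#' @param stem file-path stem; the two suffixed CSVs are written next to it.
#' @return The two paths, invisibly.
#' @export
write_summary_csv <- function(report, stem) {
  rnd <- function(v) round(v, 2)
  tg <- do.call(rbind, lapply(seq_along(report$trials), function(i) {
    tr <- report$trials[[i]]
    data.frame(trial = as.character(i), TP = tr$counts$TP, TN = tr$counts$TN,
               FP = tr$counts$FP, FN = tr$counts$FN,
               Ns_wow = tr$counts$n_soy_without_weed,
               Ps = rnd(tr$metrics$Ps), Rs = rnd(tr$metrics$Rs),
               WS = rnd(tr$metrics$WS), NT = rnd(tr$metrics$NT))
  }))
  cm <- report$counts_mean; m <- report$metrics_of_mean_counts
  tg <- rbind(tg, data.frame(trial = "average", TP = cm$TP, TN = cm$TN,
                             FP = cm$FP, FN = cm$FN,
                             Ns_wow = cm$n_soy_without_weed,
                             Ps = rnd(m$Ps), Rs = rnd(m$Rs), WS = rnd(m$WS),
                             NT = rnd(m$NT)))
  p1 <- paste0(stem, "_targeting.csv")
  utils::write.csv(tg, p1, row.names = FALSE)
  vol <- report$volume
  vr <- do.call(rbind, lapply(seq_along(vol$per_row), function(r) {
    v <- vol$per_row[[r]]
    data.frame(row = as.character(r), n_weed = report$weed_population[r],
               n_valve = rnd(v$n_valve),
               valve_per_weed = rnd(v$n_valve / report$weed_population[r]),
               q_variable = round(v$q_variable, 3), svr = rnd(v$svr))
  }))
  va <- vol$all
  vr <- rbind(vr, data.frame(row = "all", n_weed = sum(report$weed_population),
                             n_valve = rnd(va$n_valve),
                             valve_per_weed = rnd(va$n_valve /
                                                    sum(report$weed_population)),
                             q_variable = round(va$q_variable, 3),
                             svr = rnd(va$svr)))
  p2 <- paste0(stem, "_volume.csv")
  utils::write.csv(vr, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Replay a detection log through the control loop
#'
#' Runs exactly the scheduler path used on simulated streams, but with the
#' frame-centre position integrated from the estimated velocity (the log
#' carries no ground truth). When the log has `truth_id`s and a matching
#' `field_plot` is supplied, targeting counts are computed from the fired
#' footprints; otherwise metrics are limited to valve counts and volumes.
#'
#' @param detections a `detection_stream` or path to a detection log CSV.
#' @param cam,nozzle camera and nozzle used for the replay.
#' @param x0 assumed frame-centre position at the first frame.
#' @param plot optional `field_plot` for ground-truth scoring.
#' @param t_trial trial time used for the volume report; defaults to the
#'   log's time span.
#' @param ... passed to [run_stream()].
#' @return list: `events`, `velocity_log`, `volume` (a `volume_report`),
#'   and `counts` (`NULL` without ground truth).
#' @export
replay_detections <- function(detections, cam, nozzle, x0 = 0, plot = NULL,
                              t_trial = NULL, ...) {
  stream <- if (is.character(detections)) {
    read_detection_log(detections, fps = cam$fps)
  } else detections
  res <- run_stream(stream, cam, nozzle, truth_x = NULL, x0 = x0, ...)
  span <- if (length(stream) > 1L) {
    stream[[length(stream)]]$t - stream[[1L]]$t + 1 / cam$fps
  } else 1 / cam$fps
  vol <- volume_metrics(nrow(res$events), nozzle, t_trial %||% span)
  counts <- if (!is.null(plot)) classify_outcomes(plot, res$events) else NULL
  list(events = res$events, velocity_log = res$velocity_log,
       volume = vol, counts = counts)
}
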