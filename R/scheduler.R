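#' Nozzle specification
#'
#' Field-trial values: 1.6 L/min delivery rate, 0.2 s valve opening,
#' 0.45 m nozzle height, 1.08 m static spray pattern width. The transverse
#' half-angle follows from the pattern width (`tan(theta_T) =
#' width / (2 h)`, i.e. 1.2 at the defaults); the longitudinal half-angle
#' defaults to the same fan geometry. The nozzle axis trails the camera
#' frame centre by `offset` metres along the travel direction, so a weed is
#' detected first and reached by the nozzle `offset / v` seconds later; the
#' machine's drawings show the separation but print no number, so 0.30 m is
#' a configurable default.
#'
#' @param flow_rate_lpm nozzle delivery rate, litres/minute.
#' @param open_time_s valve opening time per spray, seconds.
#' @param height_m nozzle height above ground, metres.
#' @param pattern_width_m static spray pattern width, metres (sets
#'   `theta_T` unless `theta_T_deg` is given).
#' @param theta_T_deg,theta_L_deg transverse / longitudinal half-angles,
#'   degrees in (0, 90).
#' @param offset_m along-travel distance from frame centre back to the
#'   nozzle axis, metres (> 0).
#' @return A `nozzle_spec`.
#' @export
nozzle_spec <- function(flow_rate_lpm = 1.6, open_time_s = 0.2,
                        height_m = 0.45, pattern_width_m = 1.08,
                        theta_T_deg = NULL, theta_L_deg = NULL,
                        offset_m = 0.30) {
  if (flow_rate_lpm <= 0 || open_time_s <= 0 || height_m <= 0 || offset_m <= 0) {
    stop_param("flow_rate, open_time, height and offset must be > 0")
  }
  theta_T <- if (is.null(theta_T_deg)) {
    atan(pattern_width_m / (2 * height_m)) * 180 / pi
  } else theta_T_deg
  theta_L <- theta_L_deg %||% theta_T
  if (theta_T <= 0 || theta_T >= 90 || theta_L <= 0 || theta_L >= 90) {
    stop_param("spray half-angles must be in (0, 90) degrees")
  }
  structure(list(flow_rate_lpm = flow_rate_lpm, open_time_s = open_time_s,
                 height_m = height_m, theta_T = theta_T, theta_L = theta_L,
                 offset_m = offset_m),
            class = "nozzle_spec")
}

#' Ground footprint of one valve actuation
#'
#' One spray wets a stretched-ellipse-shaped patch with width
#' `2 h tan(theta_T)` and length `t_spraying * v + 2 h tan(theta_L)`: the
#' static fan pattern elongated by the ground covered while the valve is
#' open. At the trial operating point (0.45 m height, 1.08 m pattern,
#' 0.2 s, 0.69 m/s) this is 1.08 m x 1.218 m.
#'
#' @param nozzle a `nozzle_spec`.
#' @param v ground speed at fire time, m/s (>= 0).
#' @return Named numeric: `length` (along travel) and `width`, metres.
#' @export
footprint <- function(nozzle, v) {
  if (v < 0) stop_param("v must be >= 0")
  deg2rad <- pi / 180
  c(length = nozzle$open_time_s * v + 2 * nozzle$height_m * tan(nozzle$theta_L * deg2rad),
    width = 2 * nozzle$height_m * tan(nozzle$theta_T * deg2rad))
}

#' Create an empty spray-schedule queue
#'
#' Jobs move `pending -> fired` (the valve opened for them) or
#' `pending -> cleared` (made redundant by a previous spray's footprint).
#'
#' @return A zero-row `spray_queue` data.frame.
#' @export
spray_queue <- function() {
  structure(
    data.frame(job_id = integer(), trigger_t = numeric(), target_x = numeric(),
               source_frame = integer(), state = character()),
    class = c("spray_queue", "data.frame"))
}

#' Append spray schedules for the weeds detected in a frame
#'
#' For each weed box the along-travel ground offset of its centre ahead of
#' the frame centre is `rel = cx * gsd_x - window/2`; the nozzle trails the
#' frame centre by `offset`, so the remaining travel before the nozzle is
#' over the weed is `d = offset + rel`, and the valve trigger time is
#' `t_now + d / v`. Weeds already past the nozzle (`d <= 0`) are dropped,
#' as are (when `guard` is a previous spray event) weeds whose ground
#' position the previous footprint already wetted — the feedback-based
#' filter that prevents repeated spraying of an already-sprayed weed.
#' Nothing is scheduled while the velocity estimate is invalid.
#'
#' @param queue a `spray_queue`.
#' @param boxes data.frame of weed-class boxes (already confidence-
#'   thresholded).
#' @param vel a `velocity_estimate`.
#' @param nozzle a `nozzle_spec`.
#' @param cam a `camera_model`.
#' @param t_now current time, seconds.
#' @param sprayer_x ground position of the frame centre, metres (true in
#'   simulation, integrated from the velocity estimate in replay).
#' @param source_frame frame index recorded on the jobs.
#' @param guard optional `spray_event` (one row of an event log); new jobs
#'   with `target_x` inside its footprint x-interval are suppressed.
#' @return The extended queue.
#' @export
schedule <- function(queue, boxes, vel, nozzle, cam, t_now, sprayer_x,
                     source_frame = NA_integer_, guard = NULL) {
  if (!isTRUE(vel$valid) || is.na(vel$v) || vel$v <= 0) return(queue)
  if (nrow(boxes) == 0L) return(queue)
  cx <- (boxes$x_min + boxes$x_max) / 2
  rel <- cx * cam$gsd[["x"]] - cam$ground_window[1] / 2
  d <- nozzle$offset_m + rel
  target_x <- sprayer_x + rel
  keep <- d > 0
  if (!is.null(guard)) {
    keep <- keep & !(target_x >= guard$x_min & target_x <= guard$x_max)
  }
  if (!any(keep)) return(queue)
  next_id <- if (nrow(queue)) max(queue$job_id) + 1L else 1L
  new <- data.frame(job_id = seq.int(next_id, length.out = sum(keep)),
                    trigger_t = t_now + d[keep] / vel$v,
                    target_x = target_x[keep],
                    source_frame = as.integer(source_frame),
                    state = "pending")
  structure(rbind(queue, new), class = class(queue))
}

#' Poll the schedule queue and fire at most one elapsed job
#'
#' Emulates the parallel process that regularly checks the schedule list:
#' if any pending job's trigger time has passed, the earliest one fires a
#' spray event at `t_now` (late-elapsed jobs fire immediately rather than
#' being dropped). The event footprint is centred at the nozzle ground
#' position using the speed estimate at fire time.
#'
#' @param queue a `spray_queue`.
#' @param t_now poll time, seconds (monotone across calls).
#' @param nozzle a `nozzle_spec`.
#' @param v ground speed at fire time, m/s.
#' @param sprayer_x frame-centre ground position at `t_now`, metres.
#' @param y_center across-travel centre of the footprint (the row
#'   centreline in that row's global coordinates), metres.
#' @return list(`event` = one-row data.frame or `NULL`, `queue` = updated).
#' @export
poll <- function(queue, t_now, nozzle, v, sprayer_x, y_center = 0) {
  due <- which(queue$state == "pending" & queue$trigger_t <= t_now)
  if (length(due) == 0L) return(list(event = NULL, queue = queue))
  j <- due[which.min(queue$trigger_t[due])]
  queue$state[j] <- "fired"
  fp <- footprint(nozzle, max(0, v))
  x_c <- sprayer_x - nozzle$offset_m
  event <- data.frame(
    t_open = t_now, duration = nozzle$open_time_s,
    x_center = x_c, y_center = y_center,
    x_min = x_c - fp[["length"]] / 2, x_max = x_c + fp[["length"]] / 2,
    y_min = y_center - fp[["width"]] / 2, y_max = y_center + fp[["width"]] / 2,
    v_at_fire = v, job_id = queue$job_id[j], n_cleared = 0L)
  list(event = event, queue = queue)
}

#' Clear schedules made redundant by a fired spray
#'
#' After the sprayed-feedback signal, every still-pending job whose target
#' ground position falls inside the event's footprint x-interval is marked
#' cleared: the weed it was queued for has just been wetted. With
#' `two_d = TRUE` the full 2-D footprint rectangle is used instead of the
#' x-interval (jobs carry no y, so the x-interval is the operative test;
#' the flag exists for event logs that record `target_y`).
#'
#' @param queue a `spray_queue`.
#' @param event one-row event data.frame from [poll()].
#' @param two_d use the 2-D rectangle when jobs carry a `target_y` column.
#' @return list(`queue`, `n_cleared`).
#' @export
clear_covered <- function(queue, event, two_d = FALSE) {
  hit <- queue$state == "pending" &
    queue$target_x >= event$x_min & queue$target_x <= event$x_max
  if (two_d && "target_y" %in% names(queue)) {
    hit <- hit & queue$target_y >= event$y_min & queue$target_y <= event$y_max
  }
  queue$state[hit] <- "cleared"
  list(queue = queue, n_cleared = sum(hit))
}

#' Theoretical maximum spray instances on a row
#'
#' Back-to-back valve openings at speed `v` each cover `open_time * v`
#' metres of travel, so a fully weed-covered row of length `L` needs at
#' most `ceiling(L / (open_time * v))` actuations (73 for a 10 m row at
#' 0.2 s and 0.69 m/s).
#'
#' @param row_length metres.
#' @param nozzle a `nozzle_spec`.
#' @param v ground speed, m/s (> 0).
#' @return Integer count.
#' @export
max_spray_instances <- function(row_length, nozzle, v) {
  if (v <= 0) stop_param("v must be > 0")
  as.integer(ceiling(row_length / (nozzle$open_time_s * v)))
}

#' Check that consecutive frames leave no unseen ground
#'
#' Between two processed frames the sprayer travels `v / fps` metres; if
#' that exceeds the along-travel ground window, strips of ground are never
#' imaged and weeds there cannot be detected. Returns `TRUE` when coverage
#' is gap-free (`v / fps <= window length`); the boundary case counts as
#' covered. The default camera's ceiling is `0.95 m x 19 fps = 18.05 m/s`.
#'
#' @param cam a `camera_model`.
#' @param v ground speed, m/s.
#' @return `TRUE` if no gaps, `FALSE` otherwise.
#' @export
gap_check <- function(cam, v) {
  # small relative slack so the exact boundary counts as covered
  v / cam$fps <= cam$ground_window[1] * (1 + 1e-9)
}

#' Write a spray-event log CSV
#'
#' Columns: t_open, duration, x_center, footprint_length, footprint_width,
#' n_cleared (plus the georeferencing columns used internally).
#'
#' @param events data.frame of fired events.
#' @param path file path.
#' @export
write_event_log <- function(events, path) {
  if (nrow(events)) {
    events$footprint_length <- events$x_max - events$x_min
    events$footprint_width <- events$y_max - events$y_min
  } else {
    events$footprint_length <- numeric(0)
    events$footprint_width <- numeric(0)
  }
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
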