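#' Top-view camera model
#'
#' The camera images a fixed ground window centred on the sprayer frame
#' centre. Default 1280 x 720 px at 19 frames/s (the effective inference
#' rate of the vision module). The ground window is not printed in the
#' machine's specification table; the default 0.95 m (along travel) x
#' 0.53 m is calibrated so that window length x 19 fps equals the quoted
#' 18.05 m/s maximum operating speed of the vision module.
#'
#' @param resolution integer pair, pixels (width along travel, height).
#' @param fps frames per second, > 0.
#' @param ground_window numeric pair, metres (along-travel length,
#'   across-travel width of the imaged patch).
#' @return A `camera_model` with derived per-axis ground sampling distance
#'   `gsd` (metres/pixel).
#' @export
camera_model <- function(resolution = c(1280L, 720L), fps = 19,
                         ground_window = c(0.95, 0.53)) {
  if (fps <= 0) stop_param("fps must be > 0")
  if (any(ground_window <= 0)) stop_param("ground_window must be > 0")
  structure(
    list(resolution = as.integer(resolution), fps = fps,
         ground_window = ground_window,
         gsd = c(x = ground_window[1] / resolution[1],
                 y = ground_window[2] / resolution[2])),
    class = "camera_model")
}

#' Detection noise model
#'
#' Emulates an imperfect single-shot detector: each true box is dropped
#' independently with a per-species miss probability, survivors are
#' relabelled with the misclassification probability, box centres and sizes
#' are jittered, and Poisson "clutter" false boxes are appended. Confidence
#' scores are Beta-distributed (true boxes Beta(8,2), clutter Beta(2,4));
#' the control loop thresholds at 0.5 downstream.
#'
#' Defaults emulate the reported detector operating point: 68% per-frame
#' recall for both classes (miss 0.32), with mild jitter and clutter.
#'
#' @param miss named numeric, per-species miss probability in `[0,1]`.
#' @param misclass probability a surviving box gets the other label.
#' @param clutter_rate expected false boxes per frame (Poisson).
#' @param center_jitter_px sd of box-centre jitter, pixels.
#' @param size_jitter sd of multiplicative box-size jitter (fraction).
#' @param conf_true,conf_clutter Beta shape pairs for confidence scores.
#' @return A `noise_model`.
#' @export
noise_model <- function(miss = c(weed = 0.32, soybean = 0.32),
                        misclass = 0, clutter_rate = 0.2,
                        center_jitter_px = 3, size_jitter = 0.05,
                        conf_true = c(8, 2), conf_clutter = c(2, 4)) {
  if (any(miss < 0 | miss > 1) || misclass < 0 || misclass > 1) {
    stop_param("probabilities must be in [0, 1]")
  }
  if (clutter_rate < 0 || center_jitter_px < 0 || size_jitter < 0) {
    stop_param("rates and jitter scales must be >= 0")
  }
  structure(list(miss = miss, misclass = misclass,
                 clutter_rate = clutter_rate,
                 center_jitter_px = center_jitter_px,
                 size_jitter = size_jitter,
                 conf_true = conf_true, conf_clutter = conf_clutter),
            class = "noise_model")
}

#' Zero-noise model (perfect detector)
#' @return A `noise_model` with all rates zero.
#' @export
noiseless <- function() {
  noise_model(miss = c(weed = 0, soybean = 0), misclass = 0,
              clutter_rate = 0, center_jitter_px = 0, size_jitter = 0)
}

empty_boxes <- function() {
  data.frame(species = character(), confidence = numeric(),
             x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), truth_id = integer())
}

frame_detections <- function(frame_index, t, boxes) {
  structure(list(frame_index = as.integer(frame_index), t = t, boxes = boxes),
            class = "frame_detections")
}

#' @export
print.frame_detections <- function(x, ...) {
  cat("<frame ", x$frame_index, "> t=", format(x$t, digits = 4), "s, ",
      nrow(x$boxes), " box(es)\n", sep = "")
  invisible(x)
}

#' Project ground-truth plants of one row into a camera frame
#'
#' Pixel x runs along the travel direction from the trailing window edge
#' (origin top-left), so plants drift toward pixel x = 0 as the sprayer
#' advances. A plant contributes one box iff its centre lies inside the
#' ground window; boxes are clipped to the frame and carry confidence 1 and
#' the plant id.
#'
#' @param plot a `field_plot`.
#' @param cam a `camera_model`.
#' @param sprayer_x ground position of the frame centre, metres.
#' @param t frame timestamp, seconds.
#' @param frame_index integer frame number.
#' @param row which row's scalable unit is imaging (row index in the plot).
#' @return A `frame_detections` object with `truth_id` filled.
#' @export
project_truth <- function(plot, cam, sprayer_x, t, frame_index = 0L, row = 1L) {
  win_l <- cam$ground_window[1]; win_w <- cam$ground_window[2]
  p <- plot$plants[plot$plants$row == row, , drop = FALSE]
  x0 <- sprayer_x - win_l / 2
  inside <- p$x >= x0 & p$x < x0 + win_l & abs(p$y) <= win_w / 2
  p <- p[inside, , drop = FALSE]
  if (nrow(p) == 0L) return(frame_detections(frame_index, t, empty_boxes()))
  cx <- (p$x - x0) / cam$gsd[["x"]]
  cy <- (p$y + win_w / 2) / cam$gsd[["y"]]
  rx <- p$radius / cam$gsd[["x"]]
  ry <- p$radius / cam$gsd[["y"]]
  boxes <- data.frame(
    species = p$species, confidence = 1,
    x_min = pmax(0, cx - rx), y_min = pmax(0, cy - ry),
    x_max = pmin(cam$resolution[1], cx + rx),
    y_max = pmin(cam$resolution[2], cy + ry),
    truth_id = p$id)
  frame_detections(frame_index, t, boxes)
}

#' Corrupt a ground-truth frame with detector noise
#'
#' Applies the `noise_model` outcome chain: miss, relabel, jitter centre and
#' size, re-draw confidence, append clutter. Clutter boxes take a uniform
#' position in the frame and a size drawn from the surviving true boxes
#' (or the radius prior when the frame is empty); their `truth_id` is `NA`.
#'
#' @param frame a `frame_detections` with `truth_id` present.
#' @param noise a `noise_model`.
#' @param cam the `camera_model` (for frame bounds).
#' @param seed optional integer; when `NULL` the current RNG stream is used
#'   (as inside [simulate_stream()]).
#' @return A corrupted `frame_detections`.
#' @export
corrupt <- function(frame, noise, cam, seed = NULL) {
  run <- function() {
    b <- frame$boxes
    if (nrow(b) > 0L) {
      miss_p <- unname(noise$miss[b$species])
      miss_p[is.na(miss_p)] <- 0
      keep <- stats::runif(nrow(b)) >= miss_p
      b <- b[keep, , drop = FALSE]
    }
    if (nrow(b) > 0L) {
      flip <- stats::runif(nrow(b)) < noise$misclass
      b$species[flip] <- ifelse(b$species[flip] == "weed", "soybean", "weed")
      cx <- (b$x_min + b$x_max) / 2 + stats::rnorm(nrow(b), 0, noise$center_jitter_px)
      cy <- (b$y_min + b$y_max) / 2 + stats::rnorm(nrow(b), 0, noise$center_jitter_px)
      hw <- (b$x_max - b$x_min) / 2 * pmax(0.1, 1 + stats::rnorm(nrow(b), 0, noise$size_jitter))
      hh <- (b$y_max - b$y_min) / 2 * pmax(0.1, 1 + stats::rnorm(nrow(b), 0, noise$size_jitter))
      b$x_min <- pmax(0, cx - hw); b$x_max <- pmin(cam$resolution[1], cx + hw)
      b$y_min <- pmax(0, cy - hh); b$y_max <- pmin(cam$resolution[2], cy + hh)
      ok <- b$x_min < b$x_max & b$y_min < b$y_max
      b <- b[ok, , drop = FALSE]
      if (noise$center_jitter_px > 0 || noise$size_jitter > 0 ||
          any(noise$miss > 0) || noise$clutter_rate > 0) {
        b$confidence <- stats::rbeta(nrow(b), noise$conf_true[1], noise$conf_true[2])
      }
    }
    n_clut <- if (noise$clutter_rate > 0) stats::rpois(1L, noise$clutter_rate) else 0L
    if (n_clut > 0L) {
      if (nrow(b) > 0L) {
        sizes_w <- sample(b$x_max - b$x_min, n_clut, replace = TRUE)
        sizes_h <- sample(b$y_max - b$y_min, n_clut, replace = TRUE)
      } else {
        r <- stats::rlnorm(n_clut, log(0.04), 0.25)
        sizes_w <- 2 * r / cam$gsd[["x"]]; sizes_h <- 2 * r / cam$gsd[["y"]]
      }
      cx <- stats::runif(n_clut, 0, cam$resolution[1])
      cy <- stats::runif(n_clut, 0, cam$resolution[2])
      clut <- data.frame(
        species = sample(c("weed", "soybean"), n_clut, replace = TRUE),
        confidence = stats::rbeta(n_clut, noise$conf_clutter[1], noise$conf_clutter[2]),
        x_min = pmax(0, cx - sizes_w / 2), y_min = pmax(0, cy - sizes_h / 2),
        x_max = pmin(cam$resolution[1], cx + sizes_w / 2),
        y_max = pmin(cam$resolution[2], cy + sizes_h / 2),
        truth_id = NA_integer_)
      b <- rbind(b, clut)
    }
    rownames(b) <- NULL
    frame_detections(frame$frame_index, frame$t, b)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Sprayer trajectory at frame resolution
#'
#' Positions are tabulated at exact frame times `(0:(n-1))/fps`. Two kinds:
#' constant speed, or a per-frame speed drawn uniformly from `v_range`
#' (emulating the rough-terrain speed record of 0.53–0.83 m/s around the
#' 0.69 m/s average).
#'
#' @param duration seconds of travel; the stream has `ceiling(duration*fps)`
#'   frames.
#' @param fps frames per second (match the camera).
#' @param v constant ground speed, m/s (ignored when `v_range` given).
#' @param v_range length-2 numeric; per-frame speed drawn uniformly in it.
#' @param x0 starting ground position of the frame centre, metres.
#' @param seed integer, used only for `v_range` draws.
#' @return A `trajectory`: data.frame with `frame_index`, `t`, `x`, `v`.
#' @export
make_trajectory <- function(duration, fps = 19, v = 0.69, v_range = NULL,
                            x0 = 0, seed = NULL) {
  if (duration <= 0) stop_param("duration must be > 0")
  n <- as.integer(ceiling(duration * fps))
  t <- (seq_len(n) - 1L) / fps
  if (is.null(v_range)) {
    vs <- rep(v, n)
  } else {
    vs <- with_seed(derive_seed(seed %||% 0L, "trajectory"),
                    stats::runif(n, v_range[1], v_range[2]))
  }
  x <- x0 + c(0, cumsum(vs[-n] / fps))
  structure(data.frame(frame_index = seq_len(n) - 1L, t = t, x = x, v = vs),
            class = c("trajectory", "data.frame"))
}

#' Simulate a noisy detection stream over one row
#'
#' Frames at exactly `1/fps` spacing covering the trajectory; each frame is
#' `corrupt(project_truth(...))`. The trajectory must be monotone
#' non-decreasing in ground position.
#'
#' @param plot a `field_plot`.
#' @param cam a `camera_model`.
#' @param trajectory a `trajectory` from [make_trajectory()].
#' @param noise a `noise_model` (default [noiseless()]).
#' @param seed integer; fixes the noise draws.
#' @param row row index imaged by this scalable unit.
#' @return A `detection_stream`: list of `frame_detections`, with the
#'   camera, row and trajectory attached as attributes.
#' @export
simulate_stream <- function(plot, cam, trajectory, noise = noiseless(),
                            seed = 0L, row = 1L) {
  if (is.unsorted(trajectory$x)) stop_param("trajectory must be monotone non-decreasing")
  if (nrow(trajectory) > 1L) {
    dts <- diff(trajectory$t)
    stopifnot(max(abs(dts - 1 / cam$fps)) < 1e-9)
  }
  frames <- with_seed(derive_seed(seed, "noise"), {
    lapply(seq_len(nrow(trajectory)), function(i) {
      f <- project_truth(plot, cam, trajectory$x[i], trajectory$t[i],
                         frame_index = trajectory$frame_index[i], row = row)
      corrupt(f, noise, cam)
    })
  })
  structure(frames, class = "detection_stream", cam = cam, row = row,
            trajectory = trajectory)
}

#' @export
print.detection_stream <- function(x, ...) {
  nb <- sum(vapply(x, function(f) nrow(f$boxes), integer(1)))
  cat("<detection_stream> ", length(x), " frames, ", nb, " boxes\n", sep = "")
  invisible(x)
}

#' Write / read a detection log CSV
#'
#' Columns: frame_index, t, species, confidence, x_min, y_min, x_max,
#' y_max, truth_id (blank for clutter). The reader accepts logs with or
#' without the truth_id column (replay mode) and regroups rows into frames;
#' frames with no boxes are preserved via the full frame-time grid when
#' `fps` is supplied.
#'
#' @param stream a `detection_stream` or list of `frame_detections`.
#' @param path file path.
#' @export
write_detection_log <- function(stream, path) {
  rows <- lapply(stream, function(f) {
    if (nrow(f$boxes) == 0L) return(NULL)
    cbind(frame_index = f$frame_index, t = f$t, f$boxes)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    cbind(frame_index = integer(), t = numeric(), empty_boxes())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_log
#' @param fps frames/s used to reconstruct empty frames between the first
#'   and last logged frame; when `NULL` only logged frames are returned.
#' @export
read_detection_log <- function(path, fps = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "t", "species", "confidence",
            "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_param("detection log missing column(s): ",
                               paste(miss, collapse = ", "))
  if (!"truth_id" %in% names(df)) df$truth_id <- NA_integer_
  if (nrow(df) && is.unsorted(df$frame_index)) df <- df[order(df$frame_index), ]
  idx <- if (is.null(fps) || nrow(df) == 0L) sort(unique(df$frame_index)) else
    seq(min(df$frame_index), max(df$frame_index))
  frames <- lapply(idx, function(i) {
    b <- df[df$frame_index == i, need[-(1:2)], drop = FALSE]
    b$truth_id <- df$truth_id[df$frame_index == i]
    rownames(b) <- NULL
    t_i <- if (any(df$frame_index == i)) df$t[df$frame_index == i][1] else i / fps
    frame_detections(i, t_i, b)
  })
  structure(frames, class = "detection_stream")
}
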