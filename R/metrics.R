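#' Classify sampled plants against fired spray footprints
#'
#' A sampled plant counts as "sprayed" iff its ground position lies inside
#' at least one fired footprint rectangle (x-interval along travel, width
#' interval across, in across-row global coordinates so that a wide nozzle
#' pattern can spill into neighbouring rows). Sprayed sample weeds are true
#' positives, unsprayed sample weeds false negatives, sprayed sample
#' soybeans false positives and unsprayed sample soybeans true negatives.
#'
#' @param plot a `field_plot` with samples marked.
#' @param events data.frame of fired spray events (rows as produced by
#'   [poll()], with `y_center`/`y_min`/`y_max` in global-y coordinates).
#' @param shape hit-test geometry: the bounding rectangle of the stretched
#'   ellipse (default, conservative) or the stretched ellipse itself (a
#'   stadium: semicircular fan ends joined by the travel strip).
#' @return A `targeting_counts` list: `TP`, `TN`, `FP`, `FN`,
#'   `n_soy_without_weed`, plus the per-plant sprayed flags.
#' @export
classify_outcomes <- function(plot, events, shape = c("rect", "ellipse")) {
  shape <- match.arg(shape)
  p <- plot$plants
  gy <- global_y(plot)
  sprayed <- rep(FALSE, nrow(p))
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      if (shape == "rect") {
        hit <- p$x >= events$x_min[k] & p$x <= events$x_max[k] &
          gy >= events$y_min[k] & gy <= events$y_max[k]
      } else {
        # stretched ellipse = static elliptical fan swept along the travel
        # strip: inside iff within the fan ellipse around the nearest point
        # of the strip's centre segment
        half_w <- (events$y_max[k] - events$y_min[k]) / 2
        travel <- events$duration[k] * max(0, events$v_at_fire[k])
        half_l <- ((events$x_max[k] - events$x_min[k]) - travel) / 2
        seg_lo <- events$x_center[k] - travel / 2
        seg_hi <- events$x_center[k] + travel / 2
        dx <- pmax(seg_lo - p$x, 0, p$x - seg_hi) / half_l
        dy <- (gy - events$y_center[k]) / half_w
        hit <- dx^2 + dy^2 <= 1
      }
      sprayed <- sprayed | hit
    }
  }
  sw <- p$is_sample & p$species == "weed"
  ss <- p$is_sample & p$species == "soybean"
  structure(list(
    TP = sum(sw & sprayed), FN = sum(sw & !sprayed),
    FP = sum(ss & sprayed), TN = sum(ss & !sprayed),
    n_soy_without_weed = sum(p$is_without_weed),
    sprayed_ids = p$id[sprayed & p$is_sample]),
    class = "targeting_counts")
}

#' Bundle targeting confusion counts
#'
#' @param TP,TN,FP,FN non-negative counts of sprayed/unsprayed sample
#'   weeds and soybeans.
#' @param n_soy_without_weed number of sampled soybeans with no adjacent
#'   weed (the non-targeting denominator).
#' @return A `targeting_counts`.
#' @export
targeting_counts <- function(TP, TN, FP, FN, n_soy_without_weed) {
  if (any(c(TP, TN, FP, FN, n_soy_without_weed) < 0)) {
    stop_param("counts must be >= 0")
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 n_soy_without_weed = n_soy_without_weed),
            class = "targeting_counts")
}

#' Targeting metric suite from confusion counts
#'
#' Percentages: spraying precision `Ps = 100 TP/(TP+FP)` (reliability of
#' targeting weeds rather than crop), spraying recall
#' `Rs = 100 TP/(TP+FN)` (fraction of weeds receiving spray),
#' wrong-spraying rate `WS = 100 FP/(TN+FP)` (sprayed non-target crop) and
#' non-targeting rate `NT = 100 TN / Ns|wow` (unsprayed crop among those
#' with no adjacent weed). A metric with a zero denominator is `NA`
#' (undefined), never 0. Values are unrounded; round at presentation.
#'
#' @param c a `targeting_counts`.
#' @return A `targeting_metrics` list: `Ps`, `Rs`, `WS`, `NT` (percent).
#' @export
targeting_metrics <- function(c) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    Ps = pct(c$TP, c$TP + c$FP),
    Rs = pct(c$TP, c$TP + c$FN),
    WS = pct(c$FP, c$TN + c$FP),
    NT = pct(c$TN, c$n_soy_without_weed)),
    class = "targeting_metrics")
}

#' @export
print.targeting_metrics <- function(x, ...) {
  f <- function(v) if (is.na(v)) "undef" else sprintf("%.2f%%", v)
  cat("Ps=", f(x$Ps), "  Rs=", f(x$Rs), "  WS=", f(x$WS), "  NT=", f(x$NT),
      "\n", sep = "")
  invisible(x)
}

#' Spray-volume accounting for a trial row
#'
#' Variable-rate volume is actuations x per-spray volume,
#' `Q_var = N_valve x (Q_nozzle / 60) x t_spraying` (the delivery rate is
#' quoted in L/min, hence the explicit /60); the uniform-spray baseline is
#' `Q_uni = n_rows x (Q_nozzle / 60) x t_trial`; the spray volume
#' reduction is `SVR = 100 (Q_uni - Q_var) / Q_uni`. SVR is 100% with no
#' actuations and can go negative if the valve is open longer than a
#' continuous pass.
#'
#' @param n_valve valve actuation count (may be a non-integer average over
#'   trials).
#' @param nozzle a `nozzle_spec`.
#' @param t_trial trial traverse time per row, seconds (> 0).
#' @param n_rows rows aggregated into the baseline (1 for a single row).
#' @return A `volume_report`: `n_valve`, `q_variable`, `q_uniform` (L),
#'   `t_trial` (s), `svr` (percent).
#' @export
volume_metrics <- function(n_valve, nozzle, t_trial, n_rows = 1) {
  if (t_trial <= 0) stop_param("t_trial must be > 0")
  q_var <- n_valve * (nozzle$flow_rate_lpm / 60) * nozzle$open_time_s
  q_uni <- n_rows * (nozzle$flow_rate_lpm / 60) * t_trial
  structure(list(n_valve = n_valve, q_variable = q_var, q_uniform = q_uni,
                 t_trial = t_trial, svr = 100 * (q_uni - q_var) / q_uni),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("N_valve=%.2f  Q_var=%.3f L  Q_uni=%.3f L  SVR=%.2f%%\n",
              x$n_valve, x$q_variable, x$q_uniform, x$svr))
  invisible(x)
}

#' Derived machine parameters of a multi-nozzle sprayer
#'
#' Effective spray width of `n` nozzles at spacing `s` with static pattern
#' width `w` is `(n - 1) s + w` (adjacent patterns overlap 50% when
#' `s = w/2`); theoretical field capacity is width x top speed, converted
#' to hectares/hour.
#'
#' @param n_nozzles number of nozzles (>= 1).
#' @param spacing nozzle spacing, metres.
#' @param pattern_width static pattern width, metres.
#' @param v_max maximum ground speed, m/s.
#' @return Named numeric: `effective_width` (m), `field_capacity` (ha/h).
#' @export
machine_params <- function(n_nozzles, spacing, pattern_width, v_max) {
  if (n_nozzles < 1) stop_param("n_nozzles must be >= 1")
  ew <- (n_nozzles - 1) * spacing + pattern_width
  c(effective_width = ew, field_capacity = ew * v_max * 3600 / 1e4)
}

#' Intersection over union of two boxes
#'
#' @param a,b numeric vectors or one-row data.frames with `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @return IOU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  g <- function(z, n) if (is.data.frame(z) || is.list(z)) z[[n]] else z[[n]]
  ix <- max(0, min(g(a, "x_max"), g(b, "x_max")) - max(g(a, "x_min"), g(b, "x_min")))
  iy <- max(0, min(g(a, "y_max"), g(b, "y_max")) - max(g(a, "y_min"), g(b, "y_min")))
  inter <- ix * iy
  area <- function(z) (g(z, "x_max") - g(z, "x_min")) * (g(z, "y_max") - g(z, "y_min"))
  u <- area(a) + area(b) - inter
  if (u <= 0) 0 else inter / u
}

#' PASCAL VOC 2007 detection evaluation
#'
#' Detections are matched to ground truth per class (and per frame when a
#' `frame_index` column is present) greedily in order of descending
#' confidence; a detection is a true positive iff its best-IOU unmatched
#' truth reaches `iou_thr`, and each truth is matched at most once. AP is
#' the 11-point interpolated area under the precision-recall curve
#' (`mean over r in {0, 0.1, ..., 1} of max precision at recall >= r`);
#' `method = "all_points"` integrates the full interpolated curve instead.
#' mAP is the unweighted mean over classes with at least one truth; a
#' class with no truths has `NA` AP.
#'
#' @param dets data.frame of detections: `species`, `confidence`, box
#'   columns, optional `frame_index`.
#' @param truths data.frame of ground-truth boxes: `species`, box columns,
#'   optional `frame_index`.
#' @param iou_thr IOU threshold (default 0.5).
#' @param conf_thr operating confidence threshold at which the scalar
#'   precision/recall columns are reported (default 0.5).
#' @param method "voc2007" (11-point) or "all_points".
#' @return A `detection_eval`: `per_class` data.frame (`class`, `ap`,
#'   `precision`, `recall`, `n_truth`, `n_det`), `map`, and `pr_curves`
#'   (list of per-class data.frames with `recall`, `precision`,
#'   `confidence`).
#' @export
voc_ap <- function(dets, truths, iou_thr = 0.5, conf_thr = 0.5,
                   method = c("voc2007", "all_points")) {
  method <- match.arg(method)
  if (!"frame_index" %in% names(dets)) dets$frame_index <- 0L
  if (!"frame_index" %in% names(truths)) truths$frame_index <- 0L
  classes <- sort(unique(c(dets$species, truths$species)))
  per_class <- list(); curves <- list()
  for (cl in classes) {
    d <- dets[dets$species == cl, , drop = FALSE]
    g <- truths[truths$species == cl, , drop = FALSE]
    n_truth <- nrow(g)
    if (nrow(d)) d <- d[order(-d$confidence), , drop = FALSE]
    tp <- logical(nrow(d))
    g_used <- logical(nrow(g))
    for (i in seq_len(nrow(d))) {
      cand <- which(!g_used & g$frame_index == d$frame_index[i])
      if (length(cand) == 0L) next
      ious <- vapply(cand, function(j) iou(d[i, ], g[j, ]), numeric(1))
      j <- which.max(ious)
      if (ious[j] >= iou_thr) {
        tp[i] <- TRUE
        g_used[cand[j]] <- TRUE
      }
    }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
    prec <- cum_tp / pmax(1, cum_tp + cum_fp)
    rec <- if (n_truth > 0) cum_tp / n_truth else rep(NA_real_, nrow(d))
    ap <- if (n_truth == 0) NA_real_ else
      ap_from_pr(rec, prec, method)
    at <- d$confidence >= conf_thr
    op_tp <- if (any(at)) cum_tp[max(which(at))] else 0
    op_n <- sum(at)
    per_class[[cl]] <- data.frame(
      class = cl, ap = ap,
      precision = if (op_n > 0) op_tp / op_n else NA_real_,
      recall = if (n_truth > 0) op_tp / n_truth else NA_real_,
      n_truth = n_truth, n_det = nrow(d))
    curves[[cl]] <- data.frame(recall = rec, precision = prec,
                               confidence = d$confidence)
  }
  pc <- do.call(rbind, per_class)
  rownames(pc) <- NULL
  structure(list(per_class = pc,
                 map = mean(pc$ap[!is.na(pc$ap)]),
                 pr_curves = curves),
            class = "detection_eval")
}

ap_from_pr <- function(rec, prec, method) {
  if (length(rec) == 0L) return(0)
  if (method == "voc2007") {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p)) max(p) else 0
    }, numeric(1)))
  } else {
    # all-points: precision envelope integrated over recall
    mrec <- c(0, rec, 1)
    mpre <- c(0, prec, 0)
    for (i in rev(seq_len(length(mpre) - 1L))) {
      mpre[i] <- max(mpre[i], mpre[i + 1L])
    }
    idx <- which(mrec[-1] != mrec[-length(mrec)])
    sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
  }
}

#' @export
print.detection_eval <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("mAP@IOU: %.3f\n", x$map))
  invisible(x)
}

#' Evaluate a corrupted stream against its noiseless projection
#'
#' Rebuilds the ground-truth boxes frame by frame with [project_truth()]
#' and runs [voc_ap()] on the pooled detections.
#'
#' @param stream a noisy `detection_stream` (with trajectory attached).
#' @param plot the `field_plot` it was generated from.
#' @param ... passed to [voc_ap()].
#' @return A `detection_eval`.
#' @export
evaluate_stream <- function(stream, plot, ...) {
  cam <- attr(stream, "cam"); traj <- attr(stream, "trajectory")
  row <- attr(stream, "row") %||% 1L
  pool <- function(frames) {
    rows <- lapply(frames, function(f) {
      if (nrow(f$boxes) == 0L) return(NULL)
      cbind(frame_index = f$frame_index, f$boxes)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else
      cbind(frame_index = integer(), empty_boxes())
  }
  truth <- lapply(seq_len(nrow(traj)), function(i) {
    project_truth(plot, cam, traj$x[i], traj$t[i], traj$frame_index[i], row)
  })
  voc_ap(pool(stream), pool(truth), ...)
}
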