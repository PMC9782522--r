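# Shared fixtures and independent brute-force oracles.

replica_specs <- function() {
  list(row_spec(weed_density = 6.6), row_spec(weed_density = 17.8),
       row_spec(weed_density = 11.8))
}

replica_plot <- function(seed = 42) {
  mark_samples(generate_field(replica_specs(), seed = seed, exact_counts = TRUE),
               30, 30, adjacency_radius = 0.15, seed = seed)
}

# Frame built directly from a box table.
make_frame <- function(boxes, frame_index = 0L, t = 0) {
  structure(list(frame_index = as.integer(frame_index), t = t, boxes = boxes),
            class = "frame_detections")
}

box_df <- function(cx, cy, w = 40, h = 40, species = "weed",
                   confidence = 1, truth_id = seq_along(cx)) {
  data.frame(species = species, confidence = confidence,
             x_min = cx - w / 2, y_min = cy - h / 2,
             x_max = cx + w / 2, y_max = cy + h / 2,
             truth_id = truth_id)
}

# Exhaustive assignment oracle: enumerate every injective mapping of prev
# boxes (same species) to cur boxes with all pair distances within the
# gate; return the one with the most pairs, ties broken by total distance.
oracle_assignment <- function(prev, cur, gate_px) {
  pb <- prev$boxes; cb <- cur$boxes
  res <- list()
  for (sp in intersect(unique(pb$species), unique(cb$species))) {
    pi <- which(pb$species == sp); ci <- which(cb$species == sp)
    px <- (pb$x_min[pi] + pb$x_max[pi]) / 2
    py <- (pb$y_min[pi] + pb$y_max[pi]) / 2
    cx <- (cb$x_min[ci] + cb$x_max[ci]) / 2
    cy <- (cb$y_min[ci] + cb$y_max[ci]) / 2
    d <- sqrt(outer(px, cx, "-")^2 + outer(py, cy, "-")^2)
    n <- length(pi); m <- length(ci)
    best <- NULL; best_n <- -1L; best_cost <- Inf
    # enumerate assignments recursively
    rec <- function(i, used, pairs, cost) {
      if (i > n) {
        np <- if (is.null(pairs)) 0L else nrow(pairs)
        if (np > best_n || (np == best_n && cost < best_cost)) {
          best <<- pairs; best_n <<- np; best_cost <<- cost
        }
        return(invisible())
      }
      rec(i + 1L, used, pairs, cost)
      for (j in seq_len(m)) {
        if (!used[j] && d[i, j] <= gate_px) {
          used[j] <- TRUE
          rec(i + 1L, used, rbind(pairs, data.frame(i = i, j = j)), cost + d[i, j])
          used[j] <- FALSE
        }
      }
    }
    rec(1L, logical(m), NULL, 0)
    if (!is.null(best) && nrow(best)) {
      res[[sp]] <- data.frame(prev_idx = pi[best$i], cur_idx = ci[best$j],
                              species = sp)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(prev_idx = integer(), cur_idx = integer(),
                                      species = character())
  rownames(out) <- NULL
  out[order(out$prev_idx), , drop = FALSE]
}

# Naive rectangle IOU, written independently of the package version.
oracle_iou <- function(a, b) {
  w <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  h <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (w <= 0 || h <= 0) return(0)
  inter <- w * h
  inter / ((a$x_max - a$x_min) * (a$y_max - a$y_min) +
             (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter)
}

# Brute-force VOC2007 AP for a single class: explicit confidence-ordered
# matching, explicit PR points per prefix, explicit 11-point loop.
oracle_voc_ap <- function(dets, truths, iou_thr = 0.5) {
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  used <- logical(nrow(truths))
  tp <- integer(0); fp <- integer(0)
  for (i in seq_len(nrow(dets))) {
    best_j <- 0L; best_iou <- -1
    for (j in seq_len(nrow(truths))) {
      if (used[j]) next
      if (!is.null(dets$frame_index) &&
          dets$frame_index[i] != truths$frame_index[j]) next
      v <- oracle_iou(dets[i, ], truths[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_thr) {
      used[best_j] <- TRUE; tp <- c(tp, 1L); fp <- c(fp, 0L)
    } else {
      tp <- c(tp, 0L); fp <- c(fp, 1L)
    }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(truths)
  total <- 0
  for (r in seq(0, 1, by = 0.1)) {
    pmax_r <- 0
    for (k in seq_along(rec)) if (rec[k] >= r && prec[k] > pmax_r) pmax_r <- prec[k]
    total <- total + pmax_r
  }
  total / 11
}

# All-pairs point-in-rectangle spray test.
oracle_sprayed <- function(plot, events) {
  p <- plot$plants; gy <- global_y(plot)
  sapply(seq_len(nrow(p)), function(i) {
    for (k in seq_len(nrow(events))) {
      if (p$x[i] >= events$x_min[k] && p$x[i] <= events$x_max[k] &&
          gy[i] >= events$y_min[k] && gy[i] <= events$y_max[k]) return(TRUE)
    }
    FALSE
  })
}
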