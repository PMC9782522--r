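#' Associate boxes between two consecutive frames
#'
#' Same-species greedy nearest-neighbour matching on box-centre Euclidean
#' distance: repeatedly take the globally closest unmatched pair until no
#' pair within `gate_px` remains. Each box is matched at most once. An
#' exhaustive minimum-total-distance assignment is available via
#' `method = "optimal"` (small frames only); on unambiguous frames the two
#' coincide.
#'
#' @param prev,cur `frame_detections` for consecutive frames.
#' @param gate_px matches farther apart than this are discarded (pixels).
#'   Default is twice the expected per-frame displacement at the fastest
#'   recorded ground speed (0.83 m/s) for a 19 fps, 0.95 m window camera.
#' @param method "greedy" (default) or "optimal" (exhaustive, n <= 8 per
#'   species).
#' @return data.frame with one row per match: `prev_idx`, `cur_idx` (row
#'   indices into the frames' `boxes`), `species`, `dist`, `dx_px`, `dy_px`
#'   (current minus previous centre, pixels).
#' @export
associate <- function(prev, cur, gate_px = 120, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  empty <- data.frame(prev_idx = integer(), cur_idx = integer(),
                      species = character(), dist = numeric(),
                      dx_px = numeric(), dy_px = numeric())
  pb <- prev$boxes; cb <- cur$boxes
  if (nrow(pb) == 0L || nrow(cb) == 0L) return(empty)
  out <- list()
  for (sp in intersect(unique(pb$species), unique(cb$species))) {
    pi <- which(pb$species == sp); ci <- which(cb$species == sp)
    px <- (pb$x_min[pi] + pb$x_max[pi]) / 2; py <- (pb$y_min[pi] + pb$y_max[pi]) / 2
    cx <- (cb$x_min[ci] + cb$x_max[ci]) / 2; cy <- (cb$y_min[ci] + cb$y_max[ci]) / 2
    d <- sqrt(outer(px, cx, "-")^2 + outer(py, cy, "-")^2)
    pairs <- if (method == "greedy") greedy_pairs(d, gate_px) else
      optimal_pairs(d, gate_px)
    if (nrow(pairs) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      prev_idx = pi[pairs$i], cur_idx = ci[pairs$j], species = sp,
      dist = d[cbind(pairs$i, pairs$j)],
      dx_px = cx[pairs$j] - px[pairs$i],
      dy_px = cy[pairs$j] - py[pairs$i])
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

greedy_pairs <- function(d, gate) {
  out <- list()
  d[d > gate] <- Inf
  while (any(is.finite(d))) {
    k <- which.min(d)
    i <- (k - 1L) %% nrow(d) + 1L
    j <- (k - 1L) %/% nrow(d) + 1L
    out[[length(out) + 1L]] <- c(i = i, j = j)
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  if (length(out) == 0L) data.frame(i = integer(), j = integer()) else
    as.data.frame(do.call(rbind, out))
}

# Exhaustive min-total-distance assignment with a gate; cost of leaving a
# box unmatched is 0, so the objective is (total gated distance) over all
# subsets x permutations. Only intended for small oracle fixtures.
optimal_pairs <- function(d, gate) {
  n <- nrow(d); m <- ncol(d)
  if (n > 8L || m > 8L) stop_param("optimal assignment limited to 8 boxes")
  d[d > gate] <- NA
  best <- NULL; best_cost <- Inf; best_n <- -1L
  recurse <- function(i, used_j, pairs, cost) {
    if (i > n) {
      np <- nrow(pairs)
      # prefer more matches; break ties by lower total distance
      if (np > best_n || (np == best_n && cost < best_cost)) {
        best <<- pairs; best_cost <<- cost; best_n <<- np
      }
      return(invisible())
    }
    recurse(i + 1L, used_j, pairs, cost)  # leave i unmatched
    for (j in seq_len(m)) {
      if (!used_j[j] && !is.na(d[i, j])) {
        used_j[j] <- TRUE
        recurse(i + 1L, used_j, rbind(pairs, data.frame(i = i, j = j)),
                cost + d[i, j])
        used_j[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(m), data.frame(i = integer(), j = integer()), 0)
  best
}

#' Initialise the velocity-estimator state
#'
#' The estimator keeps the last `k` per-frame speed estimates and reports
#' their rolling median, which rejects occasional wild mis-associations.
#'
#' @param k rolling-median window, frames.
#' @return A `velocity_state` list.
#' @export
velocity_tracker <- function(k = 5L) {
  structure(list(k = as.integer(k), history = numeric(0),
                 last = NA_real_, valid = FALSE),
            class = "velocity_state")
}

#' Estimate sprayer ground speed from frame-to-frame matches
#'
#' Per-match speed is the along-travel pixel displacement times the ground
#' sampling distance over the frame interval; plants drift backwards in the
#' frame as the sprayer advances, so a negative `dx_px` means forward
#' motion. The frame estimate is the median over matches; the reported
#' estimate is the rolling median of the last `k` frame estimates. With no
#' matches the previous estimate is retained and flagged invalid.
#'
#' @param matches data.frame from [associate()].
#' @param dt frame interval, seconds (> 0).
#' @param gsd_x along-travel ground sampling distance, metres/pixel.
#' @param state a `velocity_state` from [velocity_tracker()].
#' @param t timestamp attached to the estimate.
#' @return list with `estimate` (a `velocity_estimate`: `v`, `t`,
#'   `n_tracks`, `valid`) and the updated `state`.
#' @export
estimate_velocity <- function(matches, dt, gsd_x, state, t = NA_real_) {
  if (dt <= 0) stop_param("dt must be > 0")
  n <- nrow(matches)
  if (n == 0L) {
    est <- structure(list(v = state$last, t = t, n_tracks = 0L, valid = FALSE),
                     class = "velocity_estimate")
    return(list(estimate = est, state = state))
  }
  per_match <- -matches$dx_px * gsd_x / dt
  frame_v <- stats::median(per_match)
  state$history <- utils::tail(c(state$history, frame_v), state$k)
  v <- max(0, stats::median(state$history))
  state$last <- v
  state$valid <- TRUE
  est <- structure(list(v = v, t = t, n_tracks = n, valid = TRUE),
                   class = "velocity_estimate")
  list(estimate = est, state = state)
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat("<velocity_estimate> v=", if (is.na(x$v)) "NA" else format(x$v, digits = 4),
      " m/s, n_tracks=", x$n_tracks, ", valid=", x$valid, "\n", sep = "")
  invisible(x)
}

#' Write a velocity log CSV
#'
#' Columns: frame_index, t, v, n_tracks, valid.
#'
#' @param log data.frame accumulated by [run_stream()].
#' @param path file path.
#' @export
write_velocity_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
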