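cam <- camera_model()

test_that("projection places a centred plant at the frame centre and inverts to < 1 gsd", {
  plot <- generate_field(row_spec(weed_density = 0.2, soy_density = 0),
                         seed = 1, exact_counts = TRUE)
  plot$plants$x <- 5; plot$plants$y <- 0
  f <- project_truth(plot, cam, sprayer_x = 5, t = 0)
  expect_equal(nrow(f$boxes), 1L)
  expect_equal((f$boxes$x_min + f$boxes$x_max) / 2, 640, tolerance = 1e-9)
  expect_equal((f$boxes$y_min + f$boxes$y_max) / 2, 360, tolerance = 1e-9)

  # plant beyond the window is absent
  f2 <- project_truth(plot, cam, sprayer_x = 7, t = 0)
  expect_equal(nrow(f2$boxes), 0L)

  # round-trip of several in-window plants
  plot3 <- generate_field(row_spec(weed_density = 11.8), seed = 4, exact_counts = TRUE)
  x_c <- 5
  f3 <- project_truth(plot3, cam, x_c, 0)
  expect_gt(nrow(f3$boxes), 2)
  ground_x <- (f3$boxes$x_min + f3$boxes$x_max) / 2 * cam$gsd[["x"]] +
    (x_c - cam$ground_window[1] / 2)
  truth_x <- plot3$plants$x[match(f3$boxes$truth_id, plot3$plants$id)]
  # clipping at frame edges can shift a box centre; interior boxes are exact
  interior <- f3$boxes$x_min > 0 & f3$boxes$x_max < cam$resolution[1]
  expect_true(all(abs(ground_x - truth_x)[interior] < cam$gsd[["x"]]))
})

test_that("zero noise is the identity and miss=1 empties the frame", {
  plot <- generate_field(row_spec(weed_density = 11.8), seed = 4, exact_counts = TRUE)
  f <- project_truth(plot, cam, 5, 0)
  g <- corrupt(f, noiseless(), cam, seed = 1)
  expect_equal(g$boxes, f$boxes)
  all_miss <- noise_model(miss = c(weed = 1, soybean = 1), clutter_rate = 0)
  expect_equal(nrow(corrupt(f, all_miss, cam, seed = 1)$boxes), 0L)
})

test_that("empirical per-frame weed recall converges to 1 - miss", {
  plot <- generate_field(row_spec(weed_density = 17.8), seed = 2, exact_counts = TRUE)
  f <- project_truth(plot, cam, 5, 0)
  n_weed <- sum(f$boxes$species == "weed")
  expect_gt(n_weed, 3)
  nm <- noise_model(miss = c(weed = 0.32, soybean = 0.32), misclass = 0,
                    clutter_rate = 0, center_jitter_px = 0, size_jitter = 0)
  reps <- 2000L
  kept <- withr::with_seed(99, {
    sum(vapply(seq_len(reps), function(i) {
      g <- corrupt(f, nm, cam)
      sum(g$boxes$species == "weed")
    }, numeric(1)))
  })
  recall <- kept / (reps * n_weed)
  expect_equal(recall, 0.68, tolerance = 0.01 / 0.68)
})

test_that("streams tick at 1/fps and cover the trajectory", {
  plot <- generate_field(row_spec(weed_density = 11.8), seed = 4, exact_counts = TRUE)
  traj <- make_trajectory(15, fps = 19, v = 0.69, x0 = 0)
  expect_equal(nrow(traj), 285L)
  expect_equal(diff(traj$x)[1], 0.69 / 19, tolerance = 1e-12)
  st <- simulate_stream(plot, cam, traj)
  expect_length(st, 285L)
  expect_equal(vapply(st, function(f) f$t, numeric(1)), traj$t)

  bad <- traj; bad$x <- rev(bad$x)
  expect_error(simulate_stream(plot, cam, bad, noiseless()), "monotone")
})

test_that("a slow pass shows every plant in consecutive frames; a too-fast pass leaves gaps", {
  plot <- generate_field(row_spec(length = 3, weed_density = 5), seed = 6,
                         exact_counts = TRUE)
  traj <- make_trajectory(3 / 0.69 + 2, v = 0.69, x0 = -0.5)
  st <- simulate_stream(plot, cam, traj)
  seen <- table(unlist(lapply(st, function(f) f$boxes$truth_id)))
  expect_true(all(plot$plants$id %in% names(seen)))
  expect_true(all(seen >= 2))  # window length >> 2 v / fps
  expect_true(gap_check(cam, 0.69))

  # ground window shorter than the per-frame travel -> unseen plants
  fast_cam <- camera_model(ground_window = c(0.02, 0.53))
  expect_false(gap_check(fast_cam, 0.69))
  st2 <- simulate_stream(plot, fast_cam, traj)
  seen2 <- unique(unlist(lapply(st2, function(f) f$boxes$truth_id)))
  expect_lt(length(seen2), nrow(plot$plants))
})

test_that("detection logs round-trip and the reader tolerates missing truth ids", {
  plot <- generate_field(row_spec(weed_density = 11.8), seed = 4, exact_counts = TRUE)
  traj <- make_trajectory(4, v = 0.69, x0 = 2)
  st <- simulate_stream(plot, cam, traj, noise_model(), seed = 5)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_detection_log(st, p1)
  back <- read_detection_log(p1, fps = cam$fps)
  write_detection_log(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # strip truth_id -> still parses
  df <- utils::read.csv(p1)
  df$truth_id <- NULL
  utils::write.csv(df, p1, row.names = FALSE)
  naked <- read_detection_log(p1, fps = cam$fps)
  expect_true(all(is.na(naked[[1]]$boxes$truth_id)))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_detection_log(bad), "missing column")
})
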