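noz <- nozzle_spec()

test_that("targeting metrics reproduce the published trial arithmetic", {
  t3 <- targeting_metrics(targeting_counts(TP = 30, TN = 9, FP = 21, FN = 0,
                                           n_soy_without_weed = 10))
  expect_equal(t3$Ps, 100 * 30 / 51, tolerance = 1e-12)
  expect_equal(round(t3$Ps, 2), 58.82)
  expect_equal(t3$Rs, 100)
  expect_equal(round(t3$WS, 2), 70.00)
  expect_equal(t3$NT, 90)
  t1 <- targeting_metrics(targeting_counts(30, 7, 23, 0, 10))
  expect_equal(round(t1$WS, 2), 76.67)
  expect_equal(t1$NT, 70)
})

test_that("zero denominators flag metrics as undefined, not zero", {
  m <- targeting_metrics(targeting_counts(0, 0, 0, 0, 0))
  expect_true(all(is.na(unlist(m))))
  expect_error(targeting_counts(-1, 0, 0, 0, 0), ">= 0")
})

test_that("targeting metrics are invariant under uniform count scaling", {
  base <- targeting_counts(12, 3, 9, 6, 5)
  m1 <- targeting_metrics(base)
  m2 <- targeting_metrics(targeting_counts(12 * 7, 3 * 7, 9 * 7, 6 * 7, 5 * 7))
  expect_equal(unlist(m1), unlist(m2))
})

test_that("volume accounting reproduces the published row values", {
  rows <- list(c(38.33, 0.204, 48.89), c(57.33, 0.306, 23.56),
               c(41.67, 0.222, 44.44))
  for (r in rows) {
    v <- volume_metrics(r[1], noz, t_trial = 15)
    expect_equal(round(v$q_variable, 3), r[2])
    expect_equal(round(v$svr, 2), r[3])
  }
  all3 <- volume_metrics(137.33, noz, t_trial = 15, n_rows = 3)
  expect_equal(all3$q_uniform, 1.2, tolerance = 1e-12)
  expect_equal(round(all3$q_variable, 3), 0.732)
  expect_equal(round(all3$svr, 2), 38.96)
})

test_that("spray volume reduction saturates correctly and decreases in valve count", {
  expect_equal(volume_metrics(0, noz, 15)$svr, 100)
  expect_equal(volume_metrics(15 / 0.2, noz, 15)$svr, 0, tolerance = 1e-12)
  svrs <- vapply(seq(0, 100, by = 10),
                 function(n) volume_metrics(n, noz, 15)$svr, numeric(1))
  expect_true(all(diff(svrs) < 0))
  expect_lt(volume_metrics(100, noz, 15)$svr, 0)  # over-spraying
})

test_that("derived machine parameters match the specification table", {
  mp <- machine_params(3, 0.5, 1.08, 3.54)
  expect_equal(mp[["effective_width"]], 2.08, tolerance = 1e-12)
  expect_equal(round(mp[["field_capacity"]], 2), 2.65)
  expect_equal(machine_params(1, 0.5, 1.08, 1)[["effective_width"]], 1.08)
})

test_that("IOU handles identity, disjointness and partial overlap", {
  a <- data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2)
  b <- data.frame(x_min = 1, y_min = 0, x_max = 3, y_max = 2)
  cc <- data.frame(x_min = 5, y_min = 5, x_max = 6, y_max = 6)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, cc), 0)
  expect_equal(iou(a, b), 1 / 3, tolerance = 1e-12)
  expect_equal(iou(a, b), oracle_iou(a, b))
})

test_that("perfect detections score AP 1 and a hand-built toy matches the 11-point value", {
  truths <- box_df(cx = c(100, 300, 500), cy = 100, w = 50, h = 50)
  perf <- truths; perf$confidence <- c(0.9, 0.8, 0.7)
  ev <- voc_ap(perf, truths)
  expect_equal(ev$per_class$ap, 1)
  expect_equal(ev$map, 1)

  # 3 truths, 4 ranked detections: hit, miss, hit, hit -> AP = 9.25/11
  dets <- rbind(
    transform(box_df(cx = 100, cy = 100, w = 50, h = 50), confidence = 0.95),
    transform(box_df(cx = 900, cy = 600, w = 50, h = 50), confidence = 0.80),
    transform(box_df(cx = 305, cy = 100, w = 50, h = 50), confidence = 0.60),
    transform(box_df(cx = 495, cy = 100, w = 50, h = 50), confidence = 0.40))
  ev2 <- voc_ap(dets, truths)
  expect_equal(ev2$per_class$ap, 9.25 / 11, tolerance = 1e-12)
  expect_equal(ev2$per_class$ap, oracle_voc_ap(dets, truths), tolerance = 1e-12)
})

test_that("11-point AP equals the brute-force oracle on random small fixtures", {
  set.seed(77)
  for (rep in 1:25) {
    n_t <- sample(1:5, 1); n_d <- sample(1:10, 1)
    truths <- box_df(cx = runif(n_t, 100, 1100), cy = runif(n_t, 100, 600),
                     w = 80, h = 80)
    # detections: perturbed truths and random junk, random confidences
    src <- sample(n_t, n_d, replace = TRUE)
    hit <- runif(n_d) < 0.6
    dets <- box_df(cx = ifelse(hit, truths$x_min[src] + 40 + runif(n_d, -15, 15),
                               runif(n_d, 100, 1100)),
                   cy = ifelse(hit, truths$y_min[src] + 40 + runif(n_d, -15, 15),
                               runif(n_d, 100, 600)),
                   w = 80, h = 80)
    dets$confidence <- runif(n_d)
    expect_equal(voc_ap(dets, truths)$per_class$ap,
                 oracle_voc_ap(dets, truths), tolerance = 1e-12)
  }
})

test_that("a class with no ground truth gets an undefined AP and mAP averages the rest", {
  truths <- box_df(cx = c(100, 300), cy = 100, w = 50, h = 50, species = "weed")
  dets <- rbind(
    transform(box_df(cx = c(100, 300), cy = 100, w = 50, h = 50,
                     species = "weed"), confidence = 0.9),
    transform(box_df(cx = 600, cy = 300, w = 50, h = 50, species = "soybean"),
              confidence = 0.8))
  ev <- voc_ap(dets, truths)
  expect_true(is.na(ev$per_class$ap[ev$per_class$class == "soybean"]))
  expect_equal(ev$map, 1)
  # two defined classes: mAP is their unweighted mean
  truths2 <- rbind(truths, box_df(cx = 600, cy = 300, w = 50, h = 50,
                                  species = "soybean"))
  ev2 <- voc_ap(dets, truths2)
  expect_equal(ev2$map, mean(ev2$per_class$ap))
})

test_that("outcome classification equals the all-pairs point-in-rectangle oracle", {
  plot <- replica_plot(seed = 15)
  set.seed(15)
  ev <- data.frame(t_open = 1:6, duration = 0.2,
                   x_center = runif(6, 0, 10), y_center = runif(6, 0.25, 1.25),
                   v_at_fire = 0.69, job_id = 1:6, n_cleared = 0L)
  ev$x_min <- ev$x_center - 0.6; ev$x_max <- ev$x_center + 0.6
  ev$y_min <- ev$y_center - 0.54; ev$y_max <- ev$y_center + 0.54
  cts <- classify_outcomes(plot, ev)
  sp <- oracle_sprayed(plot, ev)
  p <- plot$plants
  expect_equal(cts$TP, sum(sp & p$is_sample & p$species == "weed"))
  expect_equal(cts$FN, sum(!sp & p$is_sample & p$species == "weed"))
  expect_equal(cts$FP, sum(sp & p$is_sample & p$species == "soybean"))
  expect_equal(cts$TN, sum(!sp & p$is_sample & p$species == "soybean"))

  # degenerate cases
  none <- classify_outcomes(plot, ev[0, ])
  expect_equal(none$TP + none$FP, 0L)
  expect_equal(none$FN, 30L); expect_equal(none$TN, 30L)
  everything <- ev[1, ]; everything$x_min <- -1; everything$x_max <- 11
  everything$y_min <- -1; everything$y_max <- 2
  all_cov <- classify_outcomes(plot, everything)
  expect_equal(all_cov$FN + all_cov$TN, 0L)

  # ellipse hit-test is a subset of its bounding rectangle
  ell <- classify_outcomes(plot, ev, shape = "ellipse")
  expect_lte(ell$TP + ell$FP, cts$TP + cts$FP)
})
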