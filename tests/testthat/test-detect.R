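test_that("blank and constant images segment to nothing", {
  cfg <- detector_config(pixel_size = 0.33)
  lab <- segment(matrix(5, 80, 100), cfg)
  expect_equal(max(lab), 0L)
  det <- detect_fibers(matrix(0, 80, 100), cfg)
  expect_equal(nrow(det), 0L)
  expect_equal(attr(det, "n_countable"), 0L)
})

test_that("well-separated objects give one component each", {
  one <- tibble::tibble(x = 25, y = 15, length = 10, width = 1,
                        orientation = 0.2, curvature = 0, z = 6,
                        intensity = 150)
  sc1 <- scene_spec(one, field_size = c(50, 30), pixel_size = 0.33, seed = 2)
  st <- stack_spec(n_planes = 3, z_step = 2, z_origin = 4)
  lab1 <- segment(focus_stack(render_zstack(sc1, st)),
                  detector_config(pixel_size = 0.33))
  expect_equal(max(lab1), 1L)

  two <- tibble::tibble(x = c(15, 38), y = c(10, 22),
                        length = c(9, 8), width = c(0.8, 0.9),
                        orientation = c(0.1, 1.0), curvature = 0,
                        z = c(5, 7), intensity = 150)
  sc2 <- scene_spec(two, field_size = c(50, 30), pixel_size = 0.33, seed = 3)
  lab2 <- segment(focus_stack(render_zstack(sc2, st)),
                  detector_config(pixel_size = 0.33))
  expect_equal(max(lab2), 2L)
})

test_that("skeleton morphometry recovers bar and blob geometry", {
  px <- 0.33
  m <- measure_component(bar_mask(30, 3), px)
  expect_equal(m$skeleton_length, 30 * px, tolerance = px / (30 * px) + 1e-9)
  expect_lt(abs(m$skeleton_length - 9.9), px + 1e-9)
  expect_lt(abs(m$width - 0.99), px + 1e-9)
  expect_equal(m$aspect_ratio, m$skeleton_length / m$width)
  expect_lte(m$n_skeleton_endpoints, 2L)

  # square blob: isotropic, low aspect ratio
  sq <- matrix(FALSE, 24, 24)
  sq[5:20, 5:20] <- TRUE
  b <- measure_component(sq, px)
  expect_lt(b$aspect_ratio, 3)

  # X-shaped cross: four endpoints after pruning
  xm <- measure_component(cross_mask(10), px, spur_prune_um = 1)
  expect_equal(xm$n_skeleton_endpoints, 4L)

  expect_error(measure_component(matrix(FALSE, 5, 5), px), "empty")
})

test_that("measured lengths scale with pixel size, aspect ratio does not", {
  for (mask in list(bar_mask(25, 3), cross_mask(8))) {
    m1 <- measure_component(mask, 0.33)
    m2 <- measure_component(mask, 0.66)
    expect_equal(m2$skeleton_length, 2 * m1$skeleton_length)
    expect_equal(m2$width, 2 * m1$width)
    expect_equal(m2$aspect_ratio, m1$aspect_ratio)
    expect_equal(m2$n_skeleton_endpoints, m1$n_skeleton_endpoints)
  }
})

test_that("classification applies strict conjunctive criteria in order", {
  crit <- counting_criteria()
  ok <- classify_fiber(10, 1, 10, 2, crit)
  expect_equal(ok$status, "countable")
  expect_equal(ok$reject_reason, "none")

  expect_equal(classify_fiber(4, 1, 4, 2, crit)$reject_reason, "too_short")
  expect_equal(classify_fiber(12, 1, 12, 4, crit)$reject_reason, "aggregate")
  # boundary values are rejected: strict inequalities
  expect_equal(classify_fiber(5, 1, 5, 2, crit)$reject_reason, "too_short")
  expect_equal(classify_fiber(9, 3, 3, 2, crit)$reject_reason, "too_thick")
  expect_equal(classify_fiber(9, 2.9, 3, 2, crit)$reject_reason, "low_AR")

  # flipping any single criterion from pass to fail flips the status
  pass <- list(length = c(5.1, 8, 20), width = c(0.4, 1.5, 2.9),
               ar = c(3.1, 6, 40))
  fail <- list(length = c(1, 4.9, 5), width = c(3, 3.5, 8),
               ar = c(0.8, 2.2, 3))
  for (l in pass$length) for (w in pass$width) for (a in pass$ar) {
    expect_equal(classify_fiber(l, w, a, 2, crit)$status, "countable")
    for (lf in fail$length) {
      expect_equal(classify_fiber(lf, w, a, 2, crit)$status, "rejected")
    }
    for (wf in fail$width) {
      expect_equal(classify_fiber(l, wf, a, 2, crit)$status, "rejected")
    }
    for (af in fail$ar) {
      expect_equal(classify_fiber(l, w, af, 2, crit)$status, "rejected")
    }
  }
})

test_that("confidence factors sit at 0.5 on their boundaries and saturate", {
  crit <- counting_criteria()
  # at the length boundary the length factor is exactly 0.5: removing it
  # doubles the score
  at_boundary <- confidence_score(5, 0.5, 10, 20, crit)
  off_boundary <- confidence_score(5 + 1e9, 0.5, 10, 20, crit)
  expect_equal(at_boundary / off_boundary, 0.5, tolerance = 1e-6)
  # strongly positive margins push the score toward 1
  expect_gt(confidence_score(50, 0.1, 100, 50, crit), 0.99)
})

test_that("confidence is monotone in every margin", {
  crit <- counting_criteria()
  snr_grid <- seq(0.5, 30, length.out = 25)
  conf <- confidence_score(8, 1, 8, snr_grid, crit)
  expect_true(all(diff(conf) >= 0))
  len_grid <- seq(1, 30, length.out = 25)
  expect_true(all(diff(confidence_score(len_grid, 1, 8, 10, crit)) >= 0))
  wid_grid <- seq(4, 0.1, length.out = 25)
  expect_true(all(diff(confidence_score(8, wid_grid, 8, 10, crit)) >= 0))
})

test_that("greedy centroid matching yields one-to-one pairs", {
  mk_det <- function(x, y, status = "countable") {
    tibble::tibble(detection_id = seq_along(x), x = x, y = y,
                   status = status)
  }
  mk_tru <- function(x, y, countable = TRUE) {
    tibble::tibble(fiber_id = seq_along(x), x = x, y = y,
                   countable = countable)
  }
  # perfect detections
  pr <- match_detections(mk_det(c(10, 40), c(10, 20)),
                         mk_tru(c(10.5, 40.2), c(10.1, 19.8)))
  expect_equal(c(pr$tp, pr$fp, pr$fn), c(2L, 0L, 0L))

  # two detections near one truth: one TP, one FP
  pr2 <- match_detections(mk_det(c(10, 11), c(10, 10.5)),
                          mk_tru(10.2, 10.1))
  expect_equal(c(pr2$tp, pr2$fp, pr2$fn), c(1L, 1L, 0L))
  # the closer detection wins
  expect_equal(pr2$pairs$detection_id, 1L)

  # no detections: all truths are misses
  pr3 <- match_detections(mk_det(numeric(0), numeric(0)),
                          mk_tru(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(pr3$fn, 3L)

  # particles far from any detection are true negatives
  pr4 <- match_detections(mk_det(10, 10),
                          mk_tru(10, 10),
                          particles = tibble::tibble(x = c(50, 11),
                                                     y = c(50, 10)))
  expect_equal(pr4$tn, 1L)
})

test_that("detection metrics follow their defining ratios", {
  m <- detection_metrics(list(tp = 1, fp = 1, fn = 0, tn = 0))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1.0)
  expect_equal(m$f_score, 2 / 3)

  m2 <- detection_metrics(list(tp = 9, fp = 1, fn = 1, tn = 89))
  expect_equal(m2$precision, 0.9)
  expect_equal(m2$recall, 0.9)
  expect_equal(m2$f_score, 0.9)
  expect_equal(m2$accuracy, 0.98)

  # undefined ratios are NA, not zero
  m3 <- detection_metrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(m3$precision) && is.na(m3$recall))
  expect_equal(m3$accuracy, 1.0)
})

test_that("background flag trips strictly above the particle threshold", {
  expect_false(background_flag(0))
  expect_false(background_flag(80))
  expect_true(background_flag(81))
  expect_true(background_flag(500))
  expect_false(background_flag(30, threshold = 30))
})

test_that("dataset summaries reproduce the annotation averages", {
  # per-image counts built to the published split totals
  counts <- rbind(
    data.frame(split = "training",
               fibers = rep(c(7, 6), c(529, 465)),
               particles = rep(c(87, 86), c(221, 773))),
    data.frame(split = "validation",
               fibers = rep(c(13, 12), c(21, 89)),
               particles = rep(c(113, 112), c(76, 34)))
  )
  s <- summarize_dataset(counts)
  tr <- s[s$split == "training", ]
  expect_equal(tr$total_fibers, 6493)
  expect_equal(tr$mean_fibers, 6.5)
  expect_equal(tr$total_particles, 85705)
  expect_equal(tr$mean_particles, 86.2)
  va <- s[s$split == "validation", ]
  expect_equal(va$total_particles, 12396)
  expect_equal(va$mean_particles, 112.7)

  z <- summarize_dataset(data.frame(split = "test", fibers = rep(0, 19),
                                    particles = rep(1, 19)))
  expect_equal(z$mean_fibers, 0.0)
  expect_error(summarize_dataset(data.frame()), "at least one")
})

test_that("dataset splits are seeded, exact and reported as percentages", {
  sp <- split_dataset(1123, c(994, 110, 19), seed = 4)
  expect_equal(sp$fractions$fraction_pct, c(88.5, 9.8, 1.7))
  expect_equal(as.integer(table(sp$assignment$split)[c("training",
                                                       "validation",
                                                       "test")]),
               c(994L, 110L, 19L))
  sp2 <- split_dataset(1123, c(994, 110, 19), seed = 4)
  expect_identical(sp$assignment, sp2$assignment)

  all_in <- split_dataset(10, c(10, 0, 0), seed = 1)
  expect_equal(all_in$fractions$fraction_pct[1], 100.0)
  expect_error(split_dataset(10, c(5, 4, 2), seed = 1), "sum")
})

test_that("high particle loads raise the false-positive rate", {
  st <- stack_spec(n_planes = 5, z_step = 3, z_origin = 4)
  cfg <- detector_config(pixel_size = 0.33)
  fp <- c(low = 0, high = 0)
  n_obj <- c(low = 0, high = 0)
  for (s in 1:10) {
    for (lev in c("low", "high")) {
      pm <- if (lev == "low") 25 else 110
      sc <- sample_scene(fiber_mean = 3, particle_mean = pm, seed = 3000 + s,
                         field_size = c(220, 147), pixel_size = 0.33)
      det <- detect_fibers(focus_stack(render_zstack(sc, st)), cfg)
      pr <- match_detections(det, true_countable_fibers(sc),
                             particles = sc$particles)
      fp[lev] <- fp[lev] + pr$fp
      n_obj[lev] <- n_obj[lev] + attr(det, "n_objects")
    }
  }
  expect_gt(fp[["high"]], fp[["low"]])
  # and the per-field object counts that drive the background flag differ
  expect_gt(n_obj[["high"]], n_obj[["low"]])
})
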