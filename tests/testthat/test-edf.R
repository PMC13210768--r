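test_that("sharpness is zero on flat planes and offset-invariant", {
  flat <- matrix(7.3, 20, 30)
  sm <- sharpness_map(list(flat), window_radius = 3)
  expect_equal(sm$maps[[1]], matrix(0, 20, 30))

  set.seed(3)
  p <- matrix(runif(20 * 30), 20, 30)
  a <- sharpness_map(list(p), window_radius = 2)$maps[[1]]
  b <- sharpness_map(list(p + 5), window_radius = 2)$maps[[1]]
  expect_equal(a, b)
})

test_that("a single bright pixel has maximal sharpness at that pixel", {
  p <- matrix(0, 15, 15)
  v <- 3.7
  p[8, 8] <- v
  e <- sharpness_map(list(p), window_radius = 2)$maps[[1]]
  # window at the pixel covers the full Laplacian response:
  # (-4v)^2 at the center and v^2 at each of 4 neighbours
  expect_equal(e[8, 8], 16 * v^2 + 4 * v^2)
  expect_equal(e[8, 8], max(e))
  # every maximal-sharpness pixel has the bright pixel in its window
  top <- which(e == max(e), arr.ind = TRUE)
  expect_true(all(abs(top[, 1] - 8) <= 2 & abs(top[, 2] - 8) <= 2))
})

test_that("focus stacking of identical planes returns the plane", {
  set.seed(5)
  p <- matrix(runif(40 * 40) * 100, 40, 40)
  st <- lapply(1:6, function(i) p)
  comp <- focus_stack(st, window_radius = 3, smooth_radius = 2)
  expect_identical(comp$raster, p)
  expect_true(all(comp$provenance == 1L))

  comp1 <- focus_stack(list(p))
  expect_identical(comp1$raster, p)
  expect_equal(comp1$n_planes, 1L)
})

test_that("composite equals the brute-force per-pixel argmax oracle", {
  set.seed(101)
  for (case in 1:4) {
    n_planes <- sample(2:8, 1)
    nr <- sample(c(16, 33, 64), 1)
    nc <- sample(c(16, 40, 64), 1)
    planes <- lapply(seq_len(n_planes), function(k) {
      matrix(rnorm(nr * nc, 50, 20), nr, nc)
    })
    r <- sample(1:4, 1)
    got <- focus_stack(planes, window_radius = r, smooth_radius = 0,
                       denoise_sigma = 0)
    want <- oracle_focus_stack(planes, r)
    expect_identical(got$raster, want$raster)
    expect_identical(got$provenance, want$provenance)
  }
})

test_that("two half-sharp planes fuse by per-pixel selection", {
  # plane 1 textured on the left half, plane 2 on the right
  set.seed(8)
  nr <- 30; nc <- 40
  tex <- matrix(rnorm(nr * nc, 100, 25), nr, nc)
  p1 <- matrix(100, nr, nc); p1[, 1:20] <- tex[, 1:20]
  p2 <- matrix(100, nr, nc); p2[, 21:40] <- tex[, 21:40]
  got <- focus_stack(list(p1, p2), window_radius = 2, smooth_radius = 0,
                     denoise_sigma = 0)
  want <- oracle_focus_stack(list(p1, p2), 2)
  expect_identical(got$raster, want$raster)
  # interior of each textured half must come from its own plane
  expect_true(all(got$provenance[5:25, 5:15] == 1L))
  expect_true(all(got$provenance[5:25, 25:35] == 2L))
})

test_that("the composite is at least as sharp as the best single plane over each fiber", {
  # noiseless render: sharpness then measures optical focus, not shot noise
  sc <- fixture_scene()
  zs <- render_zstack(sc, fixture_stack_spec(), noise = FALSE)
  comp <- focus_stack(zs)
  sm <- sharpness_map(zs, window_radius = 4)
  sm_comp <- sharpness_map(list(comp$raster), window_radius = 4)$maps[[1]]
  for (i in seq_len(nrow(sc$fibers))) {
    f <- sc$fibers[i, ]
    poly <- fibersense:::fiber_polyline(f$x, f$y, f$length, f$orientation,
                                        f$curvature)
    jj <- pmax(1, pmin(ncol(sm_comp), round(poly[, 1] / sc$pixel_size)))
    ii <- pmax(1, pmin(nrow(sm_comp), round(poly[, 2] / sc$pixel_size)))
    foot <- cbind(ii, jj)
    best_single <- max(vapply(sm$maps, function(m) mean(m[foot]), numeric(1)))
    expect_gte(mean(sm_comp[foot]), best_single * 0.99)
  }
})

test_that("stacking recovers fibers spread in depth better than any single plane", {
  # objects span >10 um of depth; a fiber in focus on one plane is blurred
  # beyond recognition on planes 6+ um away.  Fiber density matches the
  # instrument's per-area loading: at much higher densities fibers that are
  # separated only in depth overlap in projection and merge on the
  # composite, which is a property of projection, not of the fusion.
  st <- stack_spec(n_planes = 5, z_step = 3, z_origin = 4)
  cfg <- detector_config(pixel_size = 0.33)
  n_trials <- 40
  ok <- 0
  for (s in seq_len(n_trials)) {
    sc <- sample_scene(
      fiber_mean = 3, particle_mean = 5, seed = 5000 + s,
      field_size = c(200, 140), pixel_size = 0.33,
      length_meanlog = log(10), length_sdlog = 0.25,
      z_range = c(5, 15.5)
    )
    tr <- true_countable_fibers(sc)
    zs <- render_zstack(sc, st)
    comp <- focus_stack(zs)
    matched_ids <- function(img) {
      det <- detect_fibers(img, cfg)
      pr <- match_detections(det, tr)
      pr$pairs$fiber_id
    }
    comp_ids <- matched_ids(comp)
    superset <- TRUE
    for (k in seq_along(zs$planes)) {
      plane_ids <- matched_ids(zs$planes[[k]])
      if (!all(plane_ids %in% comp_ids)) superset <- FALSE
    }
    if (superset) ok <- ok + 1
  }
  expect_gte(ok / n_trials, 0.95)
})

test_that("degenerate stacks are rejected with clear errors", {
  expect_error(sharpness_map(list()), "empty")
  expect_error(focus_stack(list()), "empty")
  expect_error(
    sharpness_map(list(matrix(0, 4, 4), matrix(0, 5, 4))),
    "dimensions"
  )
})
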