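test_that("scene sampling is deterministic and honors empty densities", {
  empty <- sample_scene(fiber_mean = 0, particle_mean = 0, seed = 3)
  expect_equal(nrow(empty$fibers), 0L)
  expect_equal(nrow(empty$particles), 0L)

  a <- sample_scene(seed = 42)
  b <- sample_scene(seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- sample_scene(seed = 43)
  expect_false(identical(a$fibers, c$fibers))

  expect_error(sample_scene(fiber_mean = -1), "non-negative")
})

test_that("sampled object counts are calibrated to their Poisson means", {
  n_scenes <- 5000
  nf <- integer(n_scenes)
  np <- integer(n_scenes)
  for (s in seq_len(n_scenes)) {
    sc <- sample_scene(fiber_mean = 6.5, particle_mean = 12, seed = s,
                       particle_intensity_sdlog = 0.1)
    nf[s] <- nrow(sc$fibers)
    np[s] <- nrow(sc$particles)
  }
  expect_lt(abs(mean(nf) - 6.5), 3 * sd(nf) / sqrt(n_scenes))
  expect_lt(abs(mean(np) - 12), 3 * sd(np) / sqrt(n_scenes))
})

test_that("scene invariants are validated", {
  bad_fib <- fixture_fibers()
  bad_fib$x[1] <- 999
  expect_error(scene_spec(bad_fib, field_size = c(150, 100)), "inside")
  bad_fib2 <- fixture_fibers()
  bad_fib2$length[1] <- -2
  expect_error(scene_spec(bad_fib2, field_size = c(150, 100)), "positive")
})

test_that("ground-truth countability applies the three strict criteria", {
  mk <- function(length, width) {
    tibble::tibble(x = 50, y = 50, length = length, width = width,
                   orientation = 0, curvature = 0, z = 10, intensity = 100)
  }
  crit <- counting_criteria()
  sc <- function(f) scene_spec(f, field_size = c(150, 100))
  expect_true(true_countable_fibers(sc(mk(10, 1)))$countable)
  # exact boundaries fail: strict inequalities
  expect_false(true_countable_fibers(sc(mk(5, 1)))$countable)
  expect_equal(true_countable_fibers(sc(mk(5, 1)))$reason, "too_short")
  expect_false(true_countable_fibers(sc(mk(9, 3)))$countable)
  expect_equal(true_countable_fibers(sc(mk(9, 3)))$reason, "too_thick")
  expect_false(true_countable_fibers(sc(mk(6, 2.5)))$countable)
  expect_equal(true_countable_fibers(sc(mk(6, 2.5)))$reason, "low_AR")

  # agreement with brute-force evaluation over random geometry
  set.seed(77)
  for (rep in 1:20) {
    f <- tibble::tibble(
      x = 75, y = 50,
      length = runif(1, 2, 15), width = runif(1, 0.3, 4),
      orientation = runif(1, 0, pi), curvature = 0, z = 10, intensity = 1
    )
    got <- true_countable_fibers(scene_spec(f, field_size = c(150, 100)))
    want <- f$length > 5 && f$width < 3 && f$length / f$width > 3
    expect_equal(got$countable, want)
  }
})

test_that("overlapping fibers are flagged as aggregates", {
  fib <- tibble::tibble(
    x = c(50, 50, 100), y = c(50, 50, 80),
    length = c(12, 10, 9), width = c(1, 1, 0.8),
    orientation = c(0.2, 1.4, 0), curvature = 0,
    z = 10, intensity = 100
  )
  tr <- true_countable_fibers(scene_spec(fib, field_size = c(150, 100)))
  expect_equal(tr$reason[1:2], c("aggregate", "aggregate"))
  expect_false(any(tr$countable[1:2]))
  expect_true(tr$countable[3])
})

test_that("rendering is deterministic, local and linear in intensity", {
  sc <- fixture_scene()
  st <- fixture_stack_spec()
  z1 <- render_zstack(sc, st)
  z2 <- render_zstack(sc, st)
  expect_identical(serialize(z1, NULL), serialize(z2, NULL))
  expect_equal(z1$z_positions, 5 + 2 * (0:6))

  # empty scene, zero background, zero noise: exactly zero planes
  blank <- scene_spec(field_size = c(30, 20), pixel_size = 0.5,
                      background_level = 0,
                      noise = list(poisson_gain = 0, gaussian_sd = 0))
  zb <- render_zstack(blank, stack_spec(n_planes = 3))
  for (p in zb$planes) expect_equal(p, matrix(0, 40, 60))

  # one fiber, no background or noise: doubling intensity doubles the peak,
  # and pixels far from the fiber stay at zero
  one <- function(intensity) {
    f <- tibble::tibble(x = 20, y = 15, length = 8, width = 0.8,
                        orientation = 0.4, curvature = 0, z = 4,
                        intensity = intensity)
    scene_spec(f, field_size = c(40, 30), pixel_size = 0.33,
               background_level = 0,
               noise = list(poisson_gain = 0, gaussian_sd = 0))
  }
  st3 <- stack_spec(n_planes = 5, z_step = 2, z_origin = 0)
  ra <- render_zstack(one(100), st3)
  rb <- render_zstack(one(200), st3)
  expect_equal(max(rb$planes[[3]]), 2 * max(ra$planes[[3]]))
  # locality: beyond 5 blur sigmas everything is background (zero here)
  expect_equal(ra$planes[[3]][1:10, 100:121], matrix(0, 10, 22))

  # depth error
  deep <- one(100)
  deep$fibers$z <- 30
  expect_error(render_zstack(deep, st3), "z range")
})

test_that("the plane nearest a fiber's depth is the sharpest over it", {
  f <- tibble::tibble(x = 20, y = 15, length = 10, width = 0.8,
                      orientation = 0.5, curvature = 0, z = 24,
                      intensity = 150)
  sc <- scene_spec(f, field_size = c(40, 30), pixel_size = 0.33,
                   background_level = 0,
                   noise = list(poisson_gain = 0, gaussian_sd = 0))
  zs <- render_zstack(sc, stack_spec())  # 25 planes, 2 um steps from 0
  sm <- sharpness_map(zs, window_radius = 4)
  poly <- fibersense:::fiber_polyline(20, 15, 10, 0.5, 0)
  foot <- cbind(pmin(pmax(round(poly[, 2] / 0.33), 1), 90),
                pmin(pmax(round(poly[, 1] / 0.33), 1), 121))
  mean_sharp <- vapply(sm$maps, function(m) mean(m[foot]), numeric(1))
  expect_equal(which.max(mean_sharp),
               which.min(abs(zs$z_positions - 24)))
})

test_that("z-stacks round-trip through TIFF plus sidecar metadata", {
  sc <- fixture_scene()
  zs <- render_zstack(sc, stack_spec(n_planes = 4, z_step = 2, z_origin = 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(zs, path)
  back <- read_stack(path)
  expect_equal(back$z_positions, zs$z_positions)
  expect_equal(back$pixel_size, zs$pixel_size)
  for (k in seq_along(zs$planes)) {
    # planes are stored as scaled 32-bit floats
    expect_equal(back$planes[[k]], zs$planes[[k]], tolerance = 1e-6)
  }

  # single-plane stack is a valid file
  z1 <- fibersense:::new_zstack(zs$planes[1], zs$z_positions[1],
                                zs$pixel_size)
  p1 <- withr::local_tempfile(fileext = ".tif")
  write_stack(z1, p1)
  expect_equal(length(read_stack(p1)$planes), 1L)

  # corrupted metadata: plane count mismatch
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$n_planes <- 7
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "format error")
})

test_that("ground-truth CSV export mirrors the scene", {
  sc <- fixture_scene()
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- write_truth(sc, path)
  back <- read_truth(path)
  expect_equal(nrow(back), nrow(sc$fibers) + nrow(sc$particles))
  expect_equal(sum(back$class == "fiber"), 3)
  expect_equal(back$countable,
               c(as.integer(true_countable_fibers(sc)$countable), 0L, 0L))
  expect_equal(back$length_um[back$class == "fiber"], sc$fibers$length)
})
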