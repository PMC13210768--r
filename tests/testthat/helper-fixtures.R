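# Small hand-built scenes and masks shared across test files.

fixture_fibers <- function() {
  tibble::tibble(
    x = c(40, 110, 60), y = c(30, 60, 80),
    length = c(10, 8, 3), width = c(0.6, 1.0, 0.5),
    orientation = c(0.3, 1.2, 2.0), curvature = c(0.01, 0, -0.02),
    z = c(8, 14, 10), intensity = c(150, 120, 140)
  )
}

fixture_particles <- function() {
  tibble::tibble(
    x = c(90, 20), y = c(20, 70), radius = c(0.8, 1.0),
    z = c(9, 12), intensity = c(120, 100)
  )
}

fixture_scene <- function(seed = 7) {
  scene_spec(fixture_fibers(), fixture_particles(),
             field_size = c(150, 100), pixel_size = 0.33, seed = seed)
}

fixture_stack_spec <- function() stack_spec(n_planes = 7, z_step = 2, z_origin = 5)

# horizontal bar mask of given pixel dimensions, padded by 2 background px
bar_mask <- function(len_px, wid_px) {
  m <- matrix(FALSE, wid_px + 4L, len_px + 4L)
  m[3:(wid_px + 2L), 3:(len_px + 2L)] <- TRUE
  m
}

# X-shaped cross of two diagonal bars
cross_mask <- function(arm = 10L) {
  n <- 2L * arm + 5L
  m <- matrix(FALSE, n, n)
  for (d in -arm:arm) {
    i <- arm + 3L + d
    m[i, arm + 3L + d] <- TRUE
    m[i, arm + 3L - d] <- TRUE
  }
  m
}

# Independent per-pixel oracle for the focus-stacking chain, written as
# plain nested loops: replicate-padded 4-neighbour Laplacian, squared,
# summed over a (2r+1)^2 window (rows accumulated before being added),
# then a strict per-pixel argmax with ties to the lowest plane index.
oracle_sharpness <- function(p, r) {
  nr <- nrow(p); nc <- ncol(p)
  gv <- function(i, j) p[min(max(i, 1L), nr), min(max(j, 1L), nc)]
  lap <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      lap[i, j] <- (gv(i - 1L, j) + gv(i + 1L, j) +
                      gv(i, j - 1L) + gv(i, j + 1L)) - 4 * p[i, j]
    }
  }
  l2 <- lap^2
  e <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -r:r) {
        rowacc <- 0
        for (dj in -r:r) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
            rowacc <- rowacc + l2[ii, jj]
          }
        }
        acc <- acc + rowacc
      }
      e[i, j] <- acc
    }
  }
  e
}

oracle_focus_stack <- function(planes, r) {
  maps <- lapply(planes, oracle_sharpness, r = r)
  nr <- nrow(planes[[1]]); nc <- ncol(planes[[1]])
  comp <- matrix(0, nr, nc)
  prov <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- -Inf; bk <- 1L
      for (k in seq_along(maps)) {
        if (maps[[k]][i, j] > best) {
          best <- maps[[k]][i, j]
          bk <- k
        }
      }
      comp[i, j] <- planes[[bk]][i, j]
      prov[i, j] <- bk
    }
  }
  list(raster = comp, provenance = prov)
}
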