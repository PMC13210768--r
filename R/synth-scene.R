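# Quadratic-Bezier centerline of a fiber, as an n x 2 matrix of (x, y)
# points in um.  `length` is treated as arc length: the curve is first laid
# out with chord = length and sagitta = curvature * length^2 / 8, then
# rescaled about the centroid so its polyline arc length equals `length`.
fiber_polyline <- function(x, y, length, orientation, curvature,
                           step = 0.2) {
  n <- max(8L, ceiling(length / step) + 1L)
  t <- seq(0, 1, length.out = n)
  sag <- curvature * length^2 / 8
  # control points in local coordinates (chord along +x)
  p0 <- c(-length / 2, 0)
  p2 <- c(length / 2, 0)
  p1 <- c(0, 2 * sag)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  arc <- sum(sqrt(diff(bx)^2 + diff(by)^2))
  sc <- length / arc
  bx <- bx * sc
  by <- by * sc
  co <- cos(orientation)
  si <- sin(orientation)
  cbind(x + co * bx - si * by, y + si * bx + co * by)
}

polyline_arc_length <- function(p) {
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

# Minimum distance between two dense polylines (point-set approximation).
polyline_min_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

#' Ground-truth scene description
#'
#' Assembles and validates the full ground truth for one field of view:
#' fiber and particle geometry, depths and intensities plus the background
#' and noise model used for rendering.  Coordinates are um with the origin
#' at the field corner; `z` is depth below the filter surface (um).
#'
#' @param fibers Tibble with columns `x, y` (centroid, um), `length` (um),
#'   `width` (um), `orientation` (rad), `curvature` (1/um, 0 = straight),
#'   `z` (um), `intensity` (arbitrary fluorescence units).
#' @param particles Tibble with columns `x, y`, `radius` (um), `z`,
#'   `intensity`.
#' @param field_size Field of view `c(width, height)` in um; the default
#'   matches one 660 x 440 um composite field.
#' @param pixel_size Pixel pitch, um/pixel.
#' @param background_level Mean membrane background intensity.
#' @param background_texture_scale Correlation length of the membrane
#'   texture, um (the entangled-cellulose surface of a mixed-ester filter).
#' @param noise List with `poisson_gain` (units/photon; 0 disables shot
#'   noise) and `gaussian_sd` (additive read noise SD, units).
#' @param seed Integer seed controlling texture and rendering noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(fibers = empty_fibers(), particles = empty_particles(),
                       field_size = c(660, 440), pixel_size = 0.33,
                       background_level = 10,
                       background_texture_scale = 5,
                       noise = list(poisson_gain = 1,
                                    gaussian_sd = 0.02 * background_level),
                       seed = 1L) {
  fibers <- as_tibble(fibers)
  particles <- as_tibble(particles)
  check_positive(pixel_size, "pixel_size")
  check_nonneg(background_level, "background_level")
  check_positive(background_texture_scale, "background_texture_scale")
  stopifnot(length(field_size) == 2, all(field_size > 0))
  need_f <- c("x", "y", "length", "width", "orientation", "curvature",
              "z", "intensity")
  need_p <- c("x", "y", "radius", "z", "intensity")
  if (nrow(fibers) && !all(need_f %in% names(fibers))) {
    abort("`fibers` is missing required columns.")
  }
  if (nrow(particles) && !all(need_p %in% names(particles))) {
    abort("`particles` is missing required columns.")
  }
  if (nrow(fibers)) {
    if (any(fibers$length <= 0) || any(fibers$width <= 0) ||
        any(fibers$intensity <= 0)) {
      abort("fiber length, width and intensity must be positive.")
    }
    if (any(fibers$x < 0 | fibers$x > field_size[1] |
            fibers$y < 0 | fibers$y > field_size[2])) {
      abort("fiber centroids must lie inside the field.")
    }
  }
  if (nrow(particles)) {
    if (any(particles$radius <= 0) || any(particles$intensity <= 0)) {
      abort("particle radius and intensity must be positive.")
    }
    if (any(particles$x < 0 | particles$x > field_size[1] |
            particles$y < 0 | particles$y > field_size[2])) {
      abort("particle centroids must lie inside the field.")
    }
  }
  structure(
    list(
      fibers = fibers, particles = particles,
      field_size = as.numeric(field_size), pixel_size = pixel_size,
      background_level = background_level,
      background_texture_scale = background_texture_scale,
      noise = noise, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' @rdname scene_spec
#' @export
empty_fibers <- function() {
  tibble(x = numeric(), y = numeric(), length = numeric(),
         width = numeric(), orientation = numeric(), curvature = numeric(),
         z = numeric(), intensity = numeric())
}

#' @rdname scene_spec
#' @export
empty_particles <- function() {
  tibble(x = numeric(), y = numeric(), radius = numeric(),
         z = numeric(), intensity = numeric())
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %g x %g um field, %d fibers, %d particles, seed %d\n",
              x$field_size[1], x$field_size[2],
              nrow(x$fibers), nrow(x$particles), x$seed))
  invisible(x)
}

#' Draw a random ground-truth scene
#'
#' Samples one field of view: fiber and particle counts are Poisson with the
#' requested means, fiber geometry follows log-normal length/width laws with
#' uniform orientation and mild curvature, and depths are uniform over
#' `z_range` (fibers settle within roughly 10-15 um of the filter surface).
#' A fraction of particles is deposited as near-linear agglomerates of 2-5
#' touching particles, emulating the clusters of contiguous fluorescent
#' particles that high-dust air samples produce.  Object centroids are
#' placed with enough margin that whole objects lie inside the field.
#'
#' @param fiber_mean,particle_mean Expected fiber / particle counts per
#'   field.  The defaults (6.5 and 86.2) are typical per-field abundances
#'   for pulverized asbestos-containing building materials on a 660 x 440 um
#'   field; scale them with `field_size` area when simulating smaller crops.
#' @param seed Integer seed; identical seed and parameters give an
#'   identical scene.
#' @param field_size,pixel_size Field geometry passed to [scene_spec()].
#' @param length_meanlog,length_sdlog Log-normal fiber length law, um.
#' @param width_meanlog,width_sdlog Log-normal fiber width law, um
#'   (truncated at 2.8 um; stained asbestos fibers are thin).
#' @param curvature_sd SD of fiber curvature, 1/um.
#' @param z_range Depth range for object placement, um below the surface.
#' @param fiber_intensity_meanlog,fiber_intensity_sdlog Log-normal
#'   fluorescence amplitude law for fibers.
#' @param particle_radius_meanlog,particle_radius_sdlog Log-normal particle
#'   radius law, um (truncated at 1.5 um so a particle alone can never
#'   satisfy the fiber criteria).
#' @param particle_intensity_meanlog,particle_intensity_sdlog Log-normal
#'   particle amplitude law.
#' @param cluster_fraction Fraction of particles deposited in agglomerates.
#' @param background_level,background_texture_scale,noise Passed to
#'   [scene_spec()].
#' @return A [scene_spec()].
#' @export
sample_scene <- function(fiber_mean = 6.5, particle_mean = 86.2, seed = 1L,
                         field_size = c(660, 440), pixel_size = 0.33,
                         length_meanlog = log(9), length_sdlog = 0.45,
                         width_meanlog = log(0.7), width_sdlog = 0.35,
                         curvature_sd = 0.01,
                         z_range = c(6, 16),
                         fiber_intensity_meanlog = log(120),
                         fiber_intensity_sdlog = 0.3,
                         particle_radius_meanlog = log(0.8),
                         particle_radius_sdlog = 0.3,
                         particle_intensity_meanlog = log(100),
                         particle_intensity_sdlog = 0.4,
                         cluster_fraction = 0.15,
                         background_level = 10,
                         background_texture_scale = 5,
                         noise = list(poisson_gain = 1,
                                      gaussian_sd = 0.02 * background_level)) {
  check_nonneg(fiber_mean, "fiber_mean")
  check_nonneg(particle_mean, "particle_mean")
  stopifnot(length(z_range) == 2, z_range[1] >= 0, z_range[2] >= z_range[1])
  with_seed(seed, {
    n_fib <- rpois(1, fiber_mean)
    fibers <- if (n_fib > 0) {
      len <- rlnorm(n_fib, length_meanlog, length_sdlog)
      wid <- pmin(rlnorm(n_fib, width_meanlog, width_sdlog), 2.8)
      # keep the whole fiber (plus a blur margin) inside the field
      mar <- pmin(len / 2 + 2, field_size[1] / 2 - 1e-6)
      mary <- pmin(len / 2 + 2, field_size[2] / 2 - 1e-6)
      tibble(
        x = runif(n_fib, mar, field_size[1] - mar),
        y = runif(n_fib, mary, field_size[2] - mary),
        length = len,
        width = wid,
        orientation = runif(n_fib, 0, pi),
        curvature = rnorm(n_fib, 0, curvature_sd),
        z = runif(n_fib, z_range[1], z_range[2]),
        intensity = rlnorm(n_fib, fiber_intensity_meanlog,
                           fiber_intensity_sdlog)
      )
    } else {
      empty_fibers()
    }
    n_par <- rpois(1, particle_mean)
    particles <- if (n_par > 0) {
      rad <- pmin(rlnorm(n_par, particle_radius_meanlog,
                         particle_radius_sdlog), 1.5)
      inten <- rlnorm(n_par, particle_intensity_meanlog,
                      particle_intensity_sdlog)
      zz <- runif(n_par, z_range[1], z_range[2])
      px <- numeric(n_par); py <- numeric(n_par)
      i <- 1L
      while (i <= n_par) {
        in_cluster <- runif(1) < cluster_fraction
        size <- if (in_cluster) min(2L + rgeom(1, 0.5), 5L, n_par - i + 1L) else 1L
        x0 <- runif(1, 2, field_size[1] - 2)
        y0 <- runif(1, 2, field_size[2] - 2)
        if (size == 1L) {
          px[i] <- x0; py[i] <- y0
        } else {
          # near-linear agglomerate: centers spaced about one diameter apart
          th <- runif(1, 0, pi)
          idx <- i:(i + size - 1L)
          off <- (seq_len(size) - (size + 1) / 2) *
            (2 * mean(rad[idx])) * runif(size, 0.8, 1.1)
          px[idx] <- pmin(pmax(x0 + cos(th) * off +
                                 rnorm(size, 0, 0.2), 0.5),
                          field_size[1] - 0.5)
          py[idx] <- pmin(pmax(y0 + sin(th) * off +
                                 rnorm(size, 0, 0.2), 0.5),
                          field_size[2] - 0.5)
          # an agglomerate is one clump of the same material at one depth:
          # members share brightness (small jitter) and z
          inten[idx] <- inten[idx[1]] * runif(size, 0.85, 1.15)
          zz[idx] <- zz[idx[1]]
        }
        i <- i + size
      }
      tibble(x = px, y = py, radius = rad, z = zz, intensity = inten)
    } else {
      empty_particles()
    }
    scene_spec(
      fibers = fibers, particles = particles,
      field_size = field_size, pixel_size = pixel_size,
      background_level = background_level,
      background_texture_scale = background_texture_scale,
      noise = noise, seed = seed
    )
  })
}

#' Evaluate counting criteria on ground-truth fibers
#'
#' Flags each ground-truth fiber as countable or not under the standard
#' morphological criteria: strictly longer than `l_min`, strictly thinner
#' than `w_max`, aspect ratio strictly above `ar_min`.  Fibers whose
#' footprints touch (centerline distance below the sum of half-widths plus
#' `overlap_margin`) form an aggregate: per standard counting protocols
#' aggregated fibers are excluded, so members are flagged not countable
#' with reason `"aggregate"` when `criteria$exclude_aggregates` is set.
#'
#' @param scene A [scene_spec()].
#' @param criteria A [counting_criteria()].
#' @param overlap_margin Extra centerline separation (um) below which two
#'   fibers are considered touching.
#' @return The scene's fiber tibble with `fiber_id`, `countable` (logical)
#'   and `reason` (`"none"`, `"too_short"`, `"too_thick"`, `"low_AR"`,
#'   `"aggregate"`) columns appended.
#' @export
true_countable_fibers <- function(scene, criteria = counting_criteria(),
                                  overlap_margin = 0.3) {
  stopifnot(inherits(scene, "scene_spec"))
  fib <- scene$fibers
  if (nrow(fib) == 0L) {
    return(dplyr::mutate(fib, fiber_id = integer(), countable = logical(),
                         reason = character()))
  }
  ar <- fib$length / fib$width
  reason <- rep("none", nrow(fib))
  reason[!(fib$length > criteria$l_min)] <- "too_short"
  ok_w <- fib$width < criteria$w_max
  reason[reason == "none" & !ok_w] <- "too_thick"
  ok_ar <- ar > criteria$ar_min
  reason[reason == "none" & !ok_ar] <- "low_AR"
  if (isTRUE(criteria$exclude_aggregates) && nrow(fib) > 1L) {
    polys <- lapply(seq_len(nrow(fib)), function(i) {
      fiber_polyline(fib$x[i], fib$y[i], fib$length[i],
                     fib$orientation[i], fib$curvature[i])
    })
    agg <- rep(FALSE, nrow(fib))
    for (i in seq_len(nrow(fib) - 1L)) {
      for (j in (i + 1L):nrow(fib)) {
        touch_dist <- (fib$width[i] + fib$width[j]) / 2 + overlap_margin
        if (polyline_min_dist(polys[[i]], polys[[j]]) < touch_dist) {
          agg[i] <- TRUE
          agg[j] <- TRUE
        }
      }
    }
    reason[agg] <- "aggregate"
  }
  dplyr::mutate(fib,
                fiber_id = dplyr::row_number(),
                aspect_ratio = ar,
                countable = reason == "none",
                reason = reason)
}
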