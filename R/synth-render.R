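#' Z-stack acquisition geometry and defocus model
#'
#' Describes how a stack of focal planes is acquired: `n_planes` planes
#' starting at depth `z_origin` spaced `z_step` um apart (defaults: 25
#' planes at 2 um steps, spanning the depth through which filter-deposited
#' fibers are distributed).  Defocus blur is Gaussian with
#' `sigma = sqrt(sigma0^2 + (slope * dz)^2)` where `dz` is the distance from
#' the object to the focal plane: `sigma0` is the in-focus (diffraction
#' scale) width for an NA 0.6 objective at ~510 nm emission and `slope` the
#' geometric blur growth per um of defocus.
#'
#' @param n_planes Number of focal planes.
#' @param z_step Plane spacing, um.
#' @param z_origin Depth of the first plane, um.
#' @param defocus_sigma0 In-focus Gaussian blur sigma, um.
#' @param defocus_slope Blur growth, um of sigma per um of defocus.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(n_planes = 25L, z_step = 2, z_origin = 0,
                       defocus_sigma0 = 0.25, defocus_slope = 0.5) {
  check_positive(n_planes, "n_planes")
  check_positive(z_step, "z_step")
  check_nonneg(z_origin, "z_origin")
  check_positive(defocus_sigma0, "defocus_sigma0")
  check_nonneg(defocus_slope, "defocus_slope")
  structure(
    list(n_planes = as.integer(n_planes), z_step = z_step,
         z_origin = z_origin, defocus_sigma0 = defocus_sigma0,
         defocus_slope = defocus_slope),
    class = "stack_spec"
  )
}

stack_z_positions <- function(stack) {
  stack$z_origin + (seq_len(stack$n_planes) - 1L) * stack$z_step
}

defocus_sigma <- function(stack, dz) {
  sqrt(stack$defocus_sigma0^2 + (stack$defocus_slope * abs(dz))^2)
}

new_zstack <- function(planes, z_positions, pixel_size) {
  stopifnot(length(planes) == length(z_positions),
            !is.unsorted(z_positions, strictly = TRUE))
  structure(list(planes = planes, z_positions = z_positions,
                 pixel_size = pixel_size),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack> %d planes of %d x %d px, z %g..%g um, pixel %g um\n",
              length(x$planes), nrow(x$planes[[1]]), ncol(x$planes[[1]]),
              min(x$z_positions), max(x$z_positions), x$pixel_size))
  invisible(x)
}

# Add one fiber's contribution to a plane image (in place semantics via
# return).  The fiber has a Gaussian cross-profile of FWHM = width; defocus
# by a Gaussian of sigma_b turns this into a Gaussian cross-profile of
# sigma_eff = sqrt(sigma_w^2 + sigma_b^2) with the amplitude scaled by
# sigma_w / sigma_eff (flux conservation across the line).  Ends are capped
# by the same radial profile via the distance to the finite centerline.
render_fiber_plane <- function(img, fiber, sigma_b, pixel_size) {
  sigma_w <- fiber$width / (2 * sqrt(2 * log(2)))
  sigma_eff <- sqrt(sigma_w^2 + sigma_b^2)
  amp <- fiber$intensity * sigma_w / sigma_eff
  # discretization can be coarse when heavily defocused: centerline errors
  # well below sigma_eff are invisible after blurring
  poly <- fiber_polyline(fiber$x, fiber$y, fiber$length,
                         fiber$orientation, fiber$curvature,
                         step = max(0.2, sigma_eff / 3))
  pad <- 3.5 * sigma_eff
  nr <- nrow(img); nc <- ncol(img)
  j0 <- max(1L, floor((min(poly[, 1]) - pad) / pixel_size) + 1L)
  j1 <- min(nc, ceiling((max(poly[, 1]) + pad) / pixel_size))
  i0 <- max(1L, floor((min(poly[, 2]) - pad) / pixel_size) + 1L)
  i1 <- min(nr, ceiling((max(poly[, 2]) + pad) / pixel_size))
  if (j1 < j0 || i1 < i0) return(img)
  xs <- (j0:j1 - 0.5) * pixel_size
  ys <- (i0:i1 - 0.5) * pixel_size
  pxg <- rep(xs, each = length(ys))
  pyg <- rep(ys, times = length(xs))
  d2 <- rep(Inf, length(pxg))
  for (s in seq_len(nrow(poly) - 1L)) {
    ax <- poly[s, 1]; ay <- poly[s, 2]
    bx <- poly[s + 1L, 1]; by <- poly[s + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    t <- if (vv > 0) pmin(pmax(((pxg - ax) * vx + (pyg - ay) * vy) / vv, 0), 1) else 0
    dx <- pxg - (ax + t * vx)
    dy <- pyg - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  patch <- amp * exp(-d2 / (2 * sigma_eff^2))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] +
    matrix(patch, nrow = i1 - i0 + 1L)
  img
}

# Particles are rendered as isotropic Gaussian blobs of sigma = radius / 2;
# defocus widens them to sigma_eff with amplitude scaled by
# (sigma_p / sigma_eff)^2 (2-D flux conservation).
render_particle_plane <- function(img, part, sigma_b, pixel_size) {
  sigma_p <- part$radius / 2
  sigma_eff <- sqrt(sigma_p^2 + sigma_b^2)
  amp <- part$intensity * (sigma_p / sigma_eff)^2
  pad <- 3.5 * sigma_eff
  nr <- nrow(img); nc <- ncol(img)
  j0 <- max(1L, floor((part$x - pad) / pixel_size) + 1L)
  j1 <- min(nc, ceiling((part$x + pad) / pixel_size))
  i0 <- max(1L, floor((part$y - pad) / pixel_size) + 1L)
  i1 <- min(nr, ceiling((part$y + pad) / pixel_size))
  if (j1 < j0 || i1 < i0) return(img)
  xs <- (j0:j1 - 0.5) * pixel_size
  ys <- (i0:i1 - 0.5) * pixel_size
  d2 <- outer(ys - part$y, xs - part$x,
              function(dy, dx) dy * dy + dx * dx)
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * exp(-d2 / (2 * sigma_eff^2))
  img
}

#' Render a scene into a defocused z-stack
#'
#' Produces the ordered focal-plane images for a ground-truth scene.  Each
#' object contributes to every plane with a Gaussian blur of
#' `sigma = sqrt(sigma0^2 + (slope * |z_plane - z_object|)^2)`; the membrane
#' texture (a seeded low-pass noise field at the filter surface, z = 0) is
#' defocused the same way.  Per-plane noise is Poisson shot noise on the
#' noiseless signal (scaled by `poisson_gain`; 0 disables) plus additive
#' Gaussian read noise.  Rendering is deterministic given the scene seed.
#'
#' @param scene A [scene_spec()].
#' @param stack A [stack_spec()]; its depth range must cover all object
#'   depths.
#' @param noise Apply the scene's noise model (`TRUE`) or return the
#'   noiseless stack.
#' @return A `zstack`: list with `planes` (matrices indexed
#'   `[row = y, col = x]`), `z_positions` (um) and `pixel_size` (um/pixel).
#' @export
render_zstack <- function(scene, stack = stack_spec(), noise = TRUE) {
  stopifnot(inherits(scene, "scene_spec"), inherits(stack, "stack_spec"))
  zs <- stack_z_positions(stack)
  obj_z <- c(scene$fibers$z, scene$particles$z)
  if (length(obj_z) && (min(obj_z) < min(zs) || max(obj_z) > max(zs))) {
    abort("object depths fall outside the stack's z range.")
  }
  px <- scene$pixel_size
  nc <- max(1L, round(scene$field_size[1] / px))
  nr <- max(1L, round(scene$field_size[2] / px))
  with_seed(scene$seed, {
    # The membrane texture is smooth at the 5-um correlation scale, so it is
    # generated and defocused on a coarse grid and bilinearly upsampled.
    cf <- max(1L, floor(scene$background_texture_scale / px / 4))
    nrc <- ceiling(nr / cf)
    ncc <- ceiling(nc / cf)
    base_texture <- if (scene$background_level > 0) {
      tex <- matrix(rnorm(nrc * ncc), nrc, ncc)
      tex <- gauss_smooth(tex, scene$background_texture_scale / px / cf)
      tex <- tex / stats::sd(tex) * 0.3 * scene$background_level
      tex - mean(tex)
    } else {
      matrix(0, nrc, ncc)
    }
    planes <- lapply(zs, function(zp) {
      img <- if (scene$background_level > 0) {
        sig_bg <- defocus_sigma(stack, zp - 0) / px / cf
        texp <- gauss_smooth(base_texture, sig_bg)
        if (cf > 1L) texp <- EBImage::resize(texp, w = nr, h = nc)
        pmax(scene$background_level + texp, 0)
      } else {
        matrix(0, nr, nc)
      }
      if (nrow(scene$fibers)) {
        for (i in seq_len(nrow(scene$fibers))) {
          f <- scene$fibers[i, ]
          img <- render_fiber_plane(img, f, defocus_sigma(stack, zp - f$z), px)
        }
      }
      if (nrow(scene$particles)) {
        for (i in seq_len(nrow(scene$particles))) {
          p <- scene$particles[i, ]
          img <- render_particle_plane(img, p,
                                       defocus_sigma(stack, zp - p$z), px)
        }
      }
      if (noise) {
        g <- scene$noise$poisson_gain %||% 0
        s <- scene$noise$gaussian_sd %||% 0
        if (g > 0) {
          img <- matrix(rpois(length(img), pmax(img, 0) / g) * g, nr, nc)
        }
        if (s > 0) {
          img <- img + matrix(rnorm(length(img), 0, s), nr, nc)
        }
      }
      img
    })
    new_zstack(planes, zs, px)
  })
}
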