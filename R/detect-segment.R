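composite_raster <- function(image) {
  if (inherits(image, "edf_composite")) return(image$raster)
  if (is.matrix(image)) return(image)
  abort("`image` must be an `edf_composite` or a numeric matrix.")
}

composite_pixel_size <- function(image, config) {
  px <- if (inherits(image, "edf_composite")) image$pixel_size else NA_real_
  if (is.na(px)) px <- config$pixel_size
  px
}

#' Segment fluorescent objects from a composite image
#'
#' Classical intensity segmentation: the membrane background (smooth level
#' plus filter texture) is estimated by a running median whose window
#' radius exceeds any object width — fibers and particles occupy too little
#' of the window to move the median — and subtracted; the residual is
#' thresholded — by default at `min_snr` robust noise SDs (the detection
#' limit of a flattened field), or by Otsu or a fixed level, always floored
#' at the noise level so near-blank images yield nothing — and connected
#' components smaller than
#' `min_object_px` are dropped.  With `refine_halfmax` each surviving
#' component is re-thresholded at half its own peak residual, so the
#' retained mask approximates the object's full-width-at-half-maximum
#' footprint independent of how far the signal exceeds the detection
#' threshold.
#'
#' @param image An `edf_composite` (see [focus_stack()]) or numeric matrix.
#' @param config A [detector_config()].
#' @return An integer label matrix (0 = background, 1..K = components) with
#'   attributes `residual` (background-subtracted image, clipped at 0),
#'   `noise_sd` (robust noise estimate) and `threshold`.  An all-constant
#'   image gives an empty (all-zero) label map.
#' @export
segment <- function(image, config = detector_config()) {
  img <- composite_raster(image)
  if (length(img) == 0L) abort("empty image.")
  px <- composite_pixel_size(image, config)
  rad_px <- max(2L, as.integer(round(config$background_radius_um / px)))
  rng <- max(img) - min(img)
  bg <- if (rng > 0) {
    EBImage::medianFilter((img - min(img)) / rng, rad_px) * rng + min(img)
  } else {
    img
  }
  res0 <- img - bg
  noise_sd <- stats::mad(res0)
  if (!is.finite(noise_sd)) noise_sd <- 0
  res <- pmax(res0, 0)
  empty <- function() {
    lab <- matrix(0L, nrow(img), ncol(img))
    attr(lab, "residual") <- res
    attr(lab, "noise_sd") <- noise_sd
    attr(lab, "threshold") <- NA_real_
    lab
  }
  mx <- max(res)
  if (mx <= 0) return(empty())
  thr <- switch(config$threshold_method,
    fixed = config$fixed_threshold,
    otsu = EBImage::otsu(res / mx, range = c(0, 1)) * mx,
    # noise-limited: after background subtraction the field is flat, so the
    # detection limit is set by the noise floor; a global Otsu would ride up
    # with the brightest fibers and drop faint ones
    snr = config$min_snr * noise_sd
  )
  thr <- max(thr, config$min_snr * noise_sd)
  mask <- res > thr
  if (!any(mask)) return(empty())
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$min_object_px)
  if (length(keep) == 0L) return(empty())
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (config$refine_halfmax) {
    lab1 <- label8(mask)
    # smooth the refinement decision so single-pixel noise dips do not
    # fragment a fiber; the robust (95th-percentile) peak keeps one noise
    # spike from raising the cut over the plateau of a uniform fiber
    ress <- gauss_smooth(res, 0.8)
    refined <- matrix(FALSE, nrow(img), ncol(img))
    for (k in seq_len(max(lab1))) {
      comp <- lab1 == k
      peak <- stats::quantile(ress[comp], 0.95, names = FALSE)
      refined <- refined | (comp & ress >= 0.5 * peak)
    }
    mask <- refined
    # refinement can split a component; re-apply the size floor
    lab2 <- label8(mask)
    sizes <- tabulate(lab2[lab2 > 0])
    keep <- which(sizes >= config$min_object_px)
    if (length(keep) == 0L) return(empty())
    mask <- matrix(lab2 %in% keep, nrow(img), ncol(img))
  }
  lab <- label8(mask)
  storage.mode(lab) <- "integer"
  attr(lab, "residual") <- res
  attr(lab, "noise_sd") <- noise_sd
  attr(lab, "threshold") <- thr
  lab
}

# 8-connected component labeling of a logical mask (fibers are thin and
# often run diagonally, where 4-connectivity would fragment them).
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  g <- skeleton_graph(mask)
  comp <- igraph::components(g)
  lab[idx] <- as.integer(comp$membership)
  lab
}

# Guo-Hall thinning of a logical mask, vectorized over the whole matrix.
# Returns a thin 8-connected skeleton.  Guo-Hall is used rather than
# Zhang-Suen because the latter's parallel sweeps can delete 2-px-wide
# diagonal strokes outright, truncating the skeletons of thin diagonal
# fibers.  Endpoints (single neighbour) are never deleted.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(mask & FALSE)
  # pad with zeros to avoid edge bookkeeping
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nbr <- function(mm, di, dj) {
    mm[(2L + di):(nrow(p) - 1L + di), (2L + dj):(ncol(p) - 1L + dj)]
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      core <- p[2:(nrow(p) - 1L), 2:(ncol(p) - 1L)]
      p2 <- nbr(p, -1L, 0L); p3 <- nbr(p, -1L, 1L); p4 <- nbr(p, 0L, 1L)
      p5 <- nbr(p, 1L, 1L);  p6 <- nbr(p, 1L, 0L);  p7 <- nbr(p, 1L, -1L)
      p8 <- nbr(p, 0L, -1L); p9 <- nbr(p, -1L, -1L)
      # connectivity number
      cp <- ((1L - p2) & (p3 | p4)) + ((1L - p4) & (p5 | p6)) +
        ((1L - p6) & (p7 | p8)) + ((1L - p8) & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nn <- pmin(n1, n2)
      o <- if (pass == 1L) {
        ((p2 | p3 | (1L - p5)) & p4)
      } else {
        ((p6 | p7 | (1L - p9)) & p8)
      }
      cond <- core == 1L & cp == 1L & nn >= 2L & nn <= 3L & o == 0L
      if (any(cond)) {
        core[cond] <- 0L
        p[2:(nrow(p) - 1L), 2:(ncol(p) - 1L)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(p) - 1L), 2:(ncol(p) - 1L)] == 1L
}

# Build an igraph over skeleton pixels (8-connectivity, orthogonal weight 1,
# diagonal weight sqrt(2)).  Vertices are named by linear pixel index.
skeleton_graph <- function(skel) {
  idx <- which(skel)
  nr <- nrow(skel)
  if (length(idx) == 0L) return(NULL)
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  weights <- numeric(0)
  key <- function(i, j) (j - 1L) * nr + i
  id_of <- setNames(seq_along(idx), as.character(idx))
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  w_off <- c(1, 1, sqrt(2), sqrt(2))
  for (o in seq_len(nrow(offs))) {
    ni <- ii + offs[o, 1]
    nj <- jj + offs[o, 2]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= ncol(skel)
    nk <- key(ni[ok], nj[ok])
    hit <- !is.na(id_of[as.character(nk)])
    if (any(hit)) {
      from <- which(ok)[hit]
      to <- id_of[as.character(nk[hit])]
      edges <- c(edges, rbind(from, as.integer(to)))
      weights <- c(weights, rep(w_off[o], sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges, weight = weights)
  }
  igraph::set_vertex_attr(g, "row", value = ii) |>
    igraph::set_vertex_attr("col", value = jj)
}

# Prune skeleton spurs: repeatedly remove leaf branches whose path length
# to the nearest branch point is below `prune_px`.  A pure path (no branch
# points) is never pruned.
prune_skeleton_graph <- function(g, prune_px) {
  if (is.null(g) || prune_px <= 0) return(g)
  repeat {
    deg <- igraph::degree(g)
    branch <- which(deg >= 3L)
    leaves <- which(deg == 1L)
    if (length(branch) == 0L || length(leaves) == 0L) break
    d <- igraph::distances(g, v = leaves, to = branch)
    removed <- FALSE
    for (li in seq_along(leaves)) {
      dmin <- min(d[li, ])
      if (is.finite(dmin) && dmin < prune_px) {
        bi <- branch[which.min(d[li, ])]
        path <- igraph::shortest_paths(g, from = leaves[li], to = bi,
                                       output = "vpath")$vpath[[1]]
        drop <- setdiff(as.integer(path), bi)
        if (length(drop)) {
          g <- igraph::delete_vertices(g, drop)
          removed <- TRUE
          break  # indices shift; restart scan
        }
      }
    }
    if (!removed) break
  }
  g
}

#' Measure one segmented component
#'
#' Skeleton-based morphometry of a connected component: the mask is thinned
#' to a medial-axis skeleton (Zhang-Suen), spurs shorter than
#' `spur_prune_um` are pruned, and
#' \itemize{
#'   \item `skeleton_length` = (longest geodesic path through the skeleton,
#'     plus one pixel for the half-pixel caps, plus the medial-axis inset
#'     at each path tip so thinning artifacts at blunt ends do not shorten
#'     the measurement) x `pixel_size`;
#'   \item `width` = (2 x median Euclidean distance-transform value over
#'     skeleton pixels - 1 px) x `pixel_size`, clamped below at one pixel;
#'   \item `aspect_ratio` = `skeleton_length / width`;
#'   \item `n_skeleton_endpoints` = degree-1 skeleton pixels after pruning
#'     (a single isolated skeleton pixel counts 1; more than 2 endpoints
#'     marks a branched, aggregate-like object).
#' }
#'
#' @param mask Logical (or 0/1) matrix of one component.
#' @param pixel_size um/pixel.
#' @param spur_prune_um Minimum retained branch length, um.
#' @return A list with `skeleton_length`, `width`, `aspect_ratio` (um, um,
#'   dimensionless) and `n_skeleton_endpoints`.
#' @export
measure_component <- function(mask, pixel_size, spur_prune_um = 1.5) {
  mask <- mask > 0
  if (!any(mask)) abort("empty component mask.")
  check_positive(pixel_size, "pixel_size")
  skel <- thin_mask(mask)
  if (!any(skel)) {
    # pathological: thinning erased everything (single pixel blobs keep one)
    skel <- mask & FALSE
    skel[which(mask)[1]] <- TRUE
  }
  g <- skeleton_graph(skel)
  dm <- EBImage::distmap(mask * 1)
  longest_path <- function(gr) {
    if (is.null(gr) || igraph::vcount(gr) <= 1L) {
      ends <- if (!is.null(gr) && igraph::vcount(gr) == 1L) {
        cbind(igraph::vertex_attr(gr, "row"), igraph::vertex_attr(gr, "col"))
      } else {
        NULL
      }
      return(list(geo = 0, ends = ends))
    }
    comp <- igraph::components(gr)
    main <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(gr, main)
    d <- igraph::distances(sub)
    d[!is.finite(d)] <- -Inf
    at <- arrayInd(which.max(d), dim(d))
    rows <- igraph::vertex_attr(sub, "row")
    cols <- igraph::vertex_attr(sub, "col")
    list(geo = max(d[is.finite(d)]),
         ends = cbind(rows[at[1, ]], cols[at[1, ]]))
  }
  # Length is taken on the raw skeleton: its longest geodesic runs out to
  # the extreme tips, so rounded end caps are measured in full.  Thinning
  # can still stop short of the mask boundary (notably at square-cut ends);
  # the medial-axis inset at each path tip — its distance-transform value —
  # is added back so the measured length tracks the full mask extent.
  lp <- longest_path(g)
  geo <- lp$geo
  cap <- 0
  if (!is.null(lp$ends)) {
    cap <- sum(pmax(dm[lp$ends] - 0.5, 0))
  }
  # Endpoint counting uses the pruned skeleton: thinning artifacts at the
  # caps would otherwise inflate the endpoint count of a simple fiber.
  gp <- prune_skeleton_graph(g, spur_prune_um / pixel_size)
  if (is.null(gp) || igraph::vcount(gp) <= 1L) {
    n_end <- 1L
  } else {
    comp <- igraph::components(gp)
    main <- which(comp$membership == which.max(comp$csize))
    deg <- igraph::degree(igraph::induced_subgraph(gp, main))
    n_end <- max(1L, sum(deg == 1L))
  }
  skel_idx <- which(skel)
  width_px <- max(2 * median(dm[skel_idx]) - 1, 1)
  len <- (geo + 1 + cap) * pixel_size
  wid <- width_px * pixel_size
  list(
    skeleton_length = len,
    width = wid,
    aspect_ratio = len / wid,
    n_skeleton_endpoints = as.integer(n_end)
  )
}
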