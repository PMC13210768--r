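#' Write and read z-stacks
#'
#' A z-stack is stored as a multi-page TIFF (one 32-bit float page per focal
#' plane, values mapped affinely into `[0, 1]`) plus a JSON sidecar
#' `<path>.json` holding `pixel_size_um`, `z_positions_um`, `n_planes` and
#' the intensity mapping (`scale`, `offset`).  The round trip preserves
#' plane data to single precision and metadata exactly.
#'
#' @param stack A `zstack` (see [render_zstack()]).
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a `zstack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  offset <- min(vapply(stack$planes, min, numeric(1)))
  scale <- max(1e-12,
               max(vapply(stack$planes, max, numeric(1))) - offset)
  tiff::writeTIFF(lapply(stack$planes, function(p) (p - offset) / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    pixel_size_um = stack$pixel_size,
    z_positions_um = stack$z_positions,
    n_planes = length(stack$planes),
    scale = scale,
    offset = offset
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(sprintf("missing sidecar metadata: %s", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_planes) {
    abort(sprintf(
      "format error: file has %d planes but metadata declares %d.",
      length(pages), meta$n_planes
    ))
  }
  if (length(meta$z_positions_um) != meta$n_planes) {
    abort(sprintf(
      "format error: %d z positions for %d planes.",
      length(meta$z_positions_um), meta$n_planes
    ))
  }
  offset <- meta$offset %||% 0
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate RGB input, use ch 1
    p * meta$scale + offset
  })
  new_zstack(planes, as.numeric(meta$z_positions_um),
             as.numeric(meta$pixel_size_um))
}

#' Write and read ground-truth annotations
#'
#' Ground truth for one scene is stored as a flat CSV with one row per
#' object: `object_id`, `class` (`fiber` or `particle`), `x_um`, `y_um`,
#' `length_um`, `width_um`, `orientation_rad`, `z_um`, `intensity`,
#' `countable` (0/1; always 0 for particles).  Countability is evaluated
#' with [true_countable_fibers()] under `criteria`.
#'
#' @param scene A [scene_spec()].
#' @param path Output CSV path.
#' @param criteria A [counting_criteria()].
#' @return `write_truth()` returns the written tibble invisibly;
#'   `read_truth()` returns a tibble.
#' @export
write_truth <- function(scene, path, criteria = counting_criteria()) {
  fib <- true_countable_fibers(scene, criteria)
  rows <- dplyr::bind_rows(
    if (nrow(fib)) {
      tibble(
        object_id = paste0("fiber_", fib$fiber_id),
        class = "fiber",
        x_um = fib$x, y_um = fib$y,
        length_um = fib$length, width_um = fib$width,
        orientation_rad = fib$orientation,
        z_um = fib$z, intensity = fib$intensity,
        countable = as.integer(fib$countable)
      )
    },
    if (nrow(scene$particles)) {
      p <- scene$particles
      tibble(
        object_id = paste0("particle_", seq_len(nrow(p))),
        class = "particle",
        x_um = p$x, y_um = p$y,
        length_um = 2 * p$radius, width_um = 2 * p$radius,
        orientation_rad = 0,
        z_um = p$z, intensity = p$intensity,
        countable = 0L
      )
    }
  )
  readr::write_csv(rows, path)
  invisible(rows)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
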