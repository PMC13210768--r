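#' Detect, measure and classify fibers on a composite image
#'
#' The full counting chain on one field of view: [segment()] the composite,
#' [measure_component()] each candidate, [classify_fiber()] against the
#' counting criteria, and score each candidate with [confidence_score()].
#' A candidate enters the fiber count only if it is classified countable
#' *and* its confidence reaches `config$confidence_threshold`; candidates
#' failing only the confidence gate are reported with
#' `reject_reason = "low_confidence"`.
#'
#' @param image An `edf_composite` (see [focus_stack()]) or numeric matrix.
#' @param config A [detector_config()].
#' @param criteria A [counting_criteria()].
#' @return A tibble of class `fiber_detections`, one row per segmented
#'   candidate: `detection_id`, centroid `x`, `y` (um), bounding box
#'   `x0, y0, x1, y1` (pixels, 0-based, half-open), `skeleton_length`,
#'   `width` (um), `aspect_ratio`, `n_endpoints`, `contrast_snr`,
#'   `confidence`, `status`, `reject_reason`.  Attributes: `n_countable`
#'   (the fiber count N), `n_objects` (all segmented fluorescent objects)
#'   and `background_flag` (see [background_flag()]).
#' @export
detect_fibers <- function(image, config = detector_config(),
                          criteria = counting_criteria()) {
  lab <- segment(image, config)
  px <- composite_pixel_size(image, config)
  res <- attr(lab, "residual")
  noise_sd <- attr(lab, "noise_sd")
  n_comp <- max(lab)
  empty <- tibble(
    detection_id = integer(), x = numeric(), y = numeric(),
    x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer(),
    skeleton_length = numeric(), width = numeric(),
    aspect_ratio = numeric(), n_endpoints = integer(),
    contrast_snr = numeric(), confidence = numeric(),
    status = character(), reject_reason = character()
  )
  if (n_comp == 0L) {
    return(finish_detections(empty, 0L, config))
  }
  rows <- purrr::map(seq_len(n_comp), function(k) {
    pix <- which(lab == k)
    ii <- ((pix - 1L) %% nrow(lab)) + 1L
    jj <- ((pix - 1L) %/% nrow(lab)) + 1L
    i0 <- min(ii); i1 <- max(ii); j0 <- min(jj); j1 <- max(jj)
    # crop with a 1-px border for thinning
    sub <- matrix(FALSE, i1 - i0 + 3L, j1 - j0 + 3L)
    sub[cbind(ii - i0 + 2L, jj - j0 + 2L)] <- TRUE
    m <- measure_component(sub, px, config$spur_prune_um)
    snr <- if (is.finite(noise_sd) && noise_sd > 0) {
      max(res[pix]) / noise_sd
    } else {
      Inf
    }
    # Cap correction: the half-max footprint of a fiber carries a rounded
    # cap of about half the measured width at each tip, so the raw mask
    # extent overstates the physical length by one width.  Subtracting it
    # recovers the centerline length of the imaged fiber.
    len <- max(m$skeleton_length - m$width, 0.1 * px)
    tibble(
      detection_id = k,
      x = mean(jj - 0.5) * px,
      y = mean(ii - 0.5) * px,
      x0 = j0 - 1L, y0 = i0 - 1L, x1 = j1, y1 = i1,
      skeleton_length = len,
      width = m$width,
      aspect_ratio = len / m$width,
      n_endpoints = m$n_skeleton_endpoints,
      contrast_snr = snr
    )
  })
  det <- dplyr::bind_rows(rows)
  cls <- classify_fiber(det$skeleton_length, det$width, det$aspect_ratio,
                        det$n_endpoints, criteria)
  det <- dplyr::bind_cols(det, cls)
  det$confidence <- confidence_score(
    det$skeleton_length, det$width, det$aspect_ratio,
    pmin(det$contrast_snr, 1e6), criteria
  )
  low <- det$status == "countable" &
    det$confidence < config$confidence_threshold
  det$status[low] <- "rejected"
  det$reject_reason[low] <- "low_confidence"
  finish_detections(det, n_comp, config)
}

finish_detections <- function(det, n_objects, config) {
  attr(det, "n_countable") <- sum(det$status == "countable")
  attr(det, "n_objects") <- n_objects
  attr(det, "background_flag") <- background_flag(n_objects)
  class(det) <- c("fiber_detections", class(det))
  det
}

#' @export
print.fiber_detections <- function(x, ...) {
  cat(sprintf("<fiber_detections> %d candidates, N countable = %d%s\n",
              nrow(x), attr(x, "n_countable"),
              if (isTRUE(attr(x, "background_flag")))
                " [high-background flag]" else ""))
  NextMethod()
}

#' High-background false-positive risk flag
#'
#' Dense fields of non-fibrous fluorescent particles raise the risk that
#' chains of contiguous particles are misclassified as fibers.  The flag is
#' raised when the total number of fluorescent objects in the analyzed
#' field strictly exceeds `threshold` (default 80 per field).
#'
#' @param n_objects Total fluorescent objects detected in the field.
#' @param threshold Flag threshold (strict inequality).
#' @return Logical.
#' @examples
#' background_flag(80) # FALSE
#' background_flag(81) # TRUE
#' @export
background_flag <- function(n_objects, threshold = 80) {
  check_nonneg(n_objects, "n_objects")
  n_objects > threshold
}
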