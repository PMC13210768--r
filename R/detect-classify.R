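#' Fiber counting criteria
#'
#' The standard morphological rule for a countable fiber: length strictly
#' greater than `l_min` um, width strictly less than `w_max` um, aspect
#' ratio strictly greater than `ar_min`, all three required.  Aggregated
#' (entangled or crossing) fibers are excluded from counting when
#' `exclude_aggregates` is set.
#'
#' @param l_min Minimum length, um (exclusive).
#' @param w_max Maximum width, um (exclusive).
#' @param ar_min Minimum aspect ratio (exclusive); must exceed 1.
#' @param exclude_aggregates Exclude aggregates from the count?
#' @return An object of class `counting_criteria`.
#' @export
counting_criteria <- function(l_min = 5, w_max = 3, ar_min = 3,
                              exclude_aggregates = TRUE) {
  check_positive(l_min, "l_min")
  check_positive(w_max, "w_max")
  check_positive(ar_min, "ar_min")
  if (ar_min <= 1) abort("`ar_min` must exceed 1.")
  structure(
    list(l_min = l_min, w_max = w_max, ar_min = ar_min,
         exclude_aggregates = isTRUE(exclude_aggregates)),
    class = "counting_criteria"
  )
}

#' Detector configuration
#'
#' Tuning knobs of the morphological fiber detector: how candidate objects
#' are segmented from the composite image, how skeletons are pruned, and
#' the minimum confidence for a candidate to be counted.
#'
#' @param threshold_method `"snr"` (default: `min_snr` times the robust
#'   noise SD of the background-subtracted image), `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity threshold above the estimated
#'   background, used when `threshold_method = "fixed"`.
#' @param min_object_px Minimum component size in pixels; smaller
#'   components are discarded as noise.
#' @param spur_prune_um Skeleton spurs shorter than this (um) are pruned
#'   before measurement.
#' @param confidence_threshold Minimum confidence score in `[0, 1]` for a
#'   countable candidate to enter the fiber count.
#' @param pixel_size Pixel pitch, um/pixel, used when the input image does
#'   not carry one.
#' @param background_radius_um Radius (um) of the disc structuring element
#'   for morphological-opening background estimation; must exceed the
#'   largest object width so fibers and particles are removed from the
#'   background estimate.
#' @param min_snr Detection floor: the final threshold is at least
#'   `min_snr` times the robust noise SD of the background-subtracted
#'   image.
#' @param refine_halfmax Re-threshold each component at half its own peak
#'   amplitude.  This trims the blur skirt so measured extents track the
#'   full-width-at-half-maximum of the object rather than growing with the
#'   signal-to-threshold ratio.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(threshold_method = c("snr", "otsu", "fixed"),
                            fixed_threshold = NULL,
                            min_object_px = 12L,
                            spur_prune_um = 1.5,
                            confidence_threshold = 0.32,
                            pixel_size = 0.33,
                            background_radius_um = 5,
                            min_snr = 4,
                            refine_halfmax = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") check_positive(fixed_threshold, "fixed_threshold")
  check_positive(min_object_px, "min_object_px")
  check_nonneg(spur_prune_um, "spur_prune_um")
  check_nonneg(confidence_threshold, "confidence_threshold")
  if (confidence_threshold > 1) abort("`confidence_threshold` must be in [0, 1].")
  check_positive(pixel_size, "pixel_size")
  check_positive(background_radius_um, "background_radius_um")
  check_nonneg(min_snr, "min_snr")
  structure(
    list(threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         min_object_px = as.integer(min_object_px),
         spur_prune_um = spur_prune_um,
         confidence_threshold = confidence_threshold,
         pixel_size = pixel_size,
         background_radius_um = background_radius_um,
         min_snr = min_snr,
         refine_halfmax = isTRUE(refine_halfmax)),
    class = "detector_config"
  )
}

#' Classify a measured candidate against the counting criteria
#'
#' Applies the counting rule to measured geometry.  A candidate is
#' countable iff `length > l_min`, `width < w_max`, `aspect_ratio > ar_min`
#' and (when aggregates are excluded) its pruned skeleton has at most two
#' endpoints — a branched skeleton indicates crossing or entangled fibers.
#' The first failing rule, checked in the order length, width, aspect
#' ratio, aggregate, is reported as the rejection reason.
#'
#' @param length,width Measured skeleton length and width, um (vectorized).
#' @param aspect_ratio Measured aspect ratio.
#' @param n_endpoints Skeleton endpoint count after spur pruning.
#' @param criteria A [counting_criteria()].
#' @return A tibble with columns `status` (`"countable"`/`"rejected"`) and
#'   `reject_reason` (`"none"`, `"too_short"`, `"too_thick"`, `"low_AR"`,
#'   `"aggregate"`).
#' @export
classify_fiber <- function(length, width, aspect_ratio, n_endpoints = 2L,
                           criteria = counting_criteria()) {
  n <- max(base::length(length), base::length(width),
           base::length(aspect_ratio), base::length(n_endpoints))
  length <- rep_len(length, n)
  width <- rep_len(width, n)
  aspect_ratio <- rep_len(aspect_ratio, n)
  n_endpoints <- rep_len(n_endpoints, n)
  if (any(!is.finite(c(length, width, aspect_ratio)))) {
    abort("measured metrics must be finite.")
  }
  reason <- rep("none", n)
  reason[!(length > criteria$l_min)] <- "too_short"
  reason[reason == "none" & !(width < criteria$w_max)] <- "too_thick"
  reason[reason == "none" & !(aspect_ratio > criteria$ar_min)] <- "low_AR"
  if (criteria$exclude_aggregates) {
    reason[reason == "none" & n_endpoints > 2L] <- "aggregate"
  }
  tibble(status = ifelse(reason == "none", "countable", "rejected"),
         reject_reason = reason)
}

#' Confidence score for a fiber candidate
#'
#' A smooth score in `(0, 1)`: the product of logistic factors on the
#' margins to each counting criterion — `(length - l_min)`,
#' `(w_max - width)`, `(aspect_ratio - ar_min)` — and on the
#' object-to-background contrast (peak amplitude over noise SD).  Each
#' factor is 0.5 exactly at its boundary and the score is monotone
#' non-decreasing in every margin.  The score shares only its threshold
#' interface with neural-detector objectness values; no numeric
#' equivalence with any trained model is implied.
#'
#' @param length,width,aspect_ratio Measured geometry, um / dimensionless.
#' @param contrast_snr Peak object amplitude divided by background noise
#'   SD.
#' @param criteria A [counting_criteria()].
#' @param scales Logistic scales: `length` (um), `width` (um), `ar`
#'   (dimensionless), and the contrast midpoint `snr_mid` / scale `snr`.
#' @return Numeric vector of confidences in `(0, 1)`.
#' @export
confidence_score <- function(length, width, aspect_ratio, contrast_snr,
                             criteria = counting_criteria(),
                             scales = list(length = 1, width = 0.5, ar = 1,
                                           snr_mid = 3, snr = 1)) {
  if (any(!is.finite(c(length, width, aspect_ratio, contrast_snr)))) {
    abort("inputs must be finite.")
  }
  plogis((length - criteria$l_min) / scales$length) *
    plogis((criteria$w_max - width) / scales$width) *
    plogis((aspect_ratio - criteria$ar_min) / scales$ar) *
    plogis((contrast_snr - scales$snr_mid) / scales$snr)
}
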