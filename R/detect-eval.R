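#' Match detections against ground truth
#'
#' Greedy nearest-centroid one-to-one matching of countable detections to
#' countable ground-truth fibers: candidate pairs are considered in order
#' of increasing centroid distance and accepted while the distance is at
#' most `max_centroid_dist`.  Unmatched countable detections are false
#' positives; unmatched countable truth fibers are false negatives; truth
#' particles with no countable detection within `max_centroid_dist` are
#' true negatives.
#'
#' @param detections A `fiber_detections` tibble (see [detect_fibers()]).
#' @param truth Output of [true_countable_fibers()] (must have `x`, `y`,
#'   `countable`).
#' @param particles Optional particle truth tibble (columns `x`, `y`) for
#'   true-negative accounting.
#' @param max_centroid_dist Maximum matching distance, um.
#' @return An object of class `detection_pairing`: list with `pairs`
#'   (tibble of matched detection/truth ids and distances) and counts `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
match_detections <- function(detections, truth, particles = NULL,
                             max_centroid_dist = 3) {
  check_positive(max_centroid_dist, "max_centroid_dist")
  det <- detections[detections$status == "countable", , drop = FALSE]
  tru <- truth[truth$countable, , drop = FALSE]
  pairs <- tibble(detection_id = integer(), fiber_id = integer(),
                  dist = numeric())
  if (nrow(det) > 0L && nrow(tru) > 0L) {
    d <- sqrt(outer(det$x, tru$x, "-")^2 + outer(det$y, tru$y, "-")^2)
    ord <- order(d)
    used_d <- logical(nrow(det))
    used_t <- logical(nrow(tru))
    for (o in ord) {
      if (d[o] > max_centroid_dist) break
      di <- ((o - 1L) %% nrow(det)) + 1L
      ti <- ((o - 1L) %/% nrow(det)) + 1L
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- TRUE
        used_t[ti] <- TRUE
        pairs <- dplyr::bind_rows(pairs, tibble(
          detection_id = det$detection_id[di],
          fiber_id = tru$fiber_id[ti],
          dist = d[o]
        ))
      }
    }
  }
  tp <- nrow(pairs)
  fp <- nrow(det) - tp
  fn <- nrow(tru) - tp
  tn <- 0L
  if (!is.null(particles) && nrow(particles) > 0L) {
    if (nrow(det) > 0L) {
      dp <- sqrt(outer(particles$x, det$x, "-")^2 +
                   outer(particles$y, det$y, "-")^2)
      tn <- sum(apply(dp, 1, min) > max_centroid_dist)
    } else {
      tn <- nrow(particles)
    }
  }
  structure(
    list(pairs = pairs, tp = tp, fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn)),
    class = "detection_pairing"
  )
}

#' Detection performance metrics
#'
#' Standard per-object metrics from a confusion count: precision
#' `tp / (tp + fp)`, recall `tp / (tp + fn)`, their harmonic-mean F-score,
#' and accuracy `(tp + tn) / (tp + tn + fp + fn)` over all annotated
#' objects (fibers and particles).  Ratios with a zero denominator are
#' reported as `NA`, not 0.
#'
#' @param pairing A `detection_pairing` (see [match_detections()]) or a
#'   list/tibble with elements `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f_score`, `accuracy`.
#' @examples
#' detection_metrics(list(tp = 9, fp = 1, fn = 1, tn = 89))
#' @export
detection_metrics <- function(pairing) {
  tp <- pairing$tp; fp <- pairing$fp; fn <- pairing$fn
  tn <- pairing$tn %||% 0L
  if (any(c(tp, fp, fn, tn) < 0)) abort("counts must be non-negative.")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_score <- if (!is.na(precision) && !is.na(recall) &&
                 precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  total <- tp + tn + fp + fn
  accuracy <- if (total > 0) (tp + tn) / total else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall,
         f_score = f_score, accuracy = accuracy)
}

#' Per-split dataset summaries
#'
#' Mean object counts per image for each dataset split, reported to one
#' decimal place as annotation summaries conventionally are.
#'
#' @param counts A data frame with one row per image: a `split` column plus
#'   numeric per-image `fibers` and `particles` counts.
#' @return A tibble with `split`, `n_images`, `total_fibers`,
#'   `mean_fibers`, `total_particles`, `mean_particles`.
#' @examples
#' summarize_dataset(data.frame(split = "train", fibers = c(5, 8),
#'                              particles = c(80, 92)))
#' @export
summarize_dataset <- function(counts) {
  counts <- as.data.frame(counts)
  if (nrow(counts) == 0L) abort("`counts` must contain at least one image.")
  if (!all(c("split", "fibers", "particles") %in% names(counts))) {
    abort("`counts` needs columns `split`, `fibers`, `particles`.")
  }
  counts |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      total_fibers = sum(.data$fibers),
      mean_fibers = round(sum(.data$fibers) / dplyr::n(), 1),
      total_particles = sum(.data$particles),
      mean_particles = round(sum(.data$particles) / dplyr::n(), 1),
      .groups = "drop"
    )
}

#' Random image-level dataset split
#'
#' Randomly assigns `n_images` images to named splits of the given sizes
#' (image-level assignment under a seed, so repeated calls reproduce the
#' same split) and reports each split's percentage share to one decimal
#' place.
#'
#' @param n_images Total number of images.
#' @param split_sizes Integer sizes; must sum to `n_images`.
#' @param seed Integer seed.
#' @param split_names Names for the splits.
#' @return A list with `assignment` (tibble `image_id`, `split`) and
#'   `fractions` (tibble `split`, `n_images`, `fraction_pct`).
#' @examples
#' split_dataset(1123, c(994, 110, 19), seed = 1)$fractions
#' @export
split_dataset <- function(n_images, split_sizes, seed = 1L,
                          split_names = c("training", "validation", "test")) {
  check_positive(n_images, "n_images")
  if (length(split_sizes) != length(split_names)) {
    abort("`split_sizes` and `split_names` must have equal length.")
  }
  if (any(split_sizes < 0)) abort("split sizes must be non-negative.")
  if (sum(split_sizes) != n_images) {
    abort(sprintf("split sizes sum to %d, not n_images = %d.",
                  sum(split_sizes), n_images))
  }
  assignment <- with_seed(seed, {
    lab <- rep(split_names, times = split_sizes)
    tibble(image_id = seq_len(n_images), split = sample(lab))
  })
  pct <- round(100 * split_sizes / n_images, 1)
  fractions <- tibble(
    split = split_names,
    n_images = as.integer(split_sizes),
    fraction_pct = pct
  )
  list(assignment = assignment, fractions = fractions)
}
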