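#' Per-pair relative differences
#'
#' For each measurement pair computes the relative difference
#' `d = 100 * (x - y) / ((x + y) / 2)` in percent of the pair mean — the
#' scale-free quantity used for Bland-Altman agreement analysis when the
#' magnitude of between-method differences grows with concentration.  Pairs
#' with `x = y = 0` have an undefined ratio: they are excluded from the
#' returned differences and counted in the `n_excluded` attribute.
#'
#' @param pairs A data frame with numeric columns `method_x` and `method_y`
#'   (concentrations, f/L), e.g. from [simulate_paired_series()], or a
#'   two-column numeric data frame.
#' @return A tibble with columns `pair_id`, `method_x`, `method_y`,
#'   `pair_mean` and `rel_diff_pct`, one row per retained pair, with
#'   attribute `n_excluded` (count of all-zero pairs dropped).
#' @examples
#' relative_differences(data.frame(method_x = 2, method_y = 1)) # +66.7%
#' @export
relative_differences <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("method_x", "method_y") %in% names(pairs))) {
    if (ncol(pairs) >= 2 && all(vapply(pairs[1:2], is.numeric, logical(1)))) {
      names(pairs)[1:2] <- c("method_x", "method_y")
    } else {
      abort("`pairs` must have numeric columns `method_x` and `method_y`.")
    }
  }
  x <- pairs$method_x
  y <- pairs$method_y
  if (length(x) < 1L) abort("`pairs` must contain at least one pair.")
  if (any(is.na(x)) || any(is.na(y))) abort("missing values in `pairs`.")
  if (any(x < 0) || any(y < 0)) abort("concentrations must be non-negative.")
  keep <- !(x == 0 & y == 0)
  out <- tibble(
    pair_id = seq_along(x)[keep],
    method_x = x[keep],
    method_y = y[keep],
    pair_mean = (x[keep] + y[keep]) / 2,
    rel_diff_pct = 100 * (x[keep] - y[keep]) / ((x[keep] + y[keep]) / 2)
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Bland-Altman limits of agreement
#'
#' Computes the mean difference, the sample standard deviation (n - 1
#' denominator) and the limits of agreement `mean +/- z_mult * SD` for a set
#' of (relative) differences.  With the default `z_mult = 1.96` the limits
#' delimit the central 95% of between-method differences under normality.
#'
#' @param diffs Either a numeric vector of differences (typically percent
#'   relative differences) or the tibble returned by
#'   [relative_differences()] (its `rel_diff_pct` column is used and the
#'   pair-level data retained for plotting).
#' @param z_mult Multiplier on the SD for the limits of agreement.
#' @return An object of class `bland_altman`: list with `n_pairs_used`,
#'   `mean_rel_diff`, `sd_rel_diff`, `loa_low`, `loa_high`, `z_mult`,
#'   `n_excluded`, and (when available) the pair-level `data`.  `sd_rel_diff`
#'   and the limits are `NA` when only one difference is supplied.
#' @examples
#' ba <- bland_altman(c(66.667, -66.667))
#' ba$loa_high # +184.8
#' @export
bland_altman <- function(diffs, z_mult = 1.96) {
  check_positive(z_mult, "z_mult")
  data <- NULL
  n_excluded <- 0L
  if (is.data.frame(diffs)) {
    if (!"rel_diff_pct" %in% names(diffs)) {
      abort("data-frame input must have a `rel_diff_pct` column.")
    }
    data <- diffs
    n_excluded <- attr(diffs, "n_excluded") %||% 0L
    diffs <- diffs$rel_diff_pct
  }
  if (!is.numeric(diffs) || length(diffs) < 1L || any(is.na(diffs))) {
    abort("`diffs` must be a non-empty numeric vector without NA.")
  }
  m <- mean(diffs)
  s <- if (length(diffs) >= 2L) sd(diffs) else NA_real_
  structure(
    list(
      n_pairs_used = length(diffs),
      mean_rel_diff = m,
      sd_rel_diff = s,
      loa_low = m - z_mult * s,
      loa_high = m + z_mult * s,
      z_mult = z_mult,
      n_excluded = n_excluded,
      data = data
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman>\n")
  cat(sprintf("  pairs used: %d (excluded all-zero: %d)\n",
              x$n_pairs_used, x$n_excluded))
  cat(sprintf("  mean relative difference: %+.1f%%\n", x$mean_rel_diff))
  cat(sprintf("  limits of agreement (mean +/- %.2f SD): %.1f%% to %.1f%%\n",
              x$z_mult, x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(
    n_pairs_used = x$n_pairs_used,
    n_excluded = x$n_excluded,
    mean_rel_diff = x$mean_rel_diff,
    sd_rel_diff = x$sd_rel_diff,
    loa_low = x$loa_low,
    loa_high = x$loa_high,
    z_mult = x$z_mult
  )
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy(x)

#' Bland-Altman plot
#'
#' Scatter of relative difference against pair mean with the mean-difference
#' line (solid) and the limits of agreement (dashed), the standard layout of
#' agreement plots.  Requires the object to have been built from
#' [relative_differences()] output so pair means are available.
#'
#' @param object A `bland_altman` object carrying pair-level data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  if (is.null(object$data)) {
    abort("no pair-level data; build the object from `relative_differences()` output.")
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$rel_diff_pct)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_rel_diff,
                        colour = "red") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Mean of pair (f/L)",
                  y = "Relative difference (% of pair mean)") +
    ggplot2::theme_minimal()
}
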