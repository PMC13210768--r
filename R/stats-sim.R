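#' Expected fibers per field at a given airborne concentration
#'
#' Inverts the count-to-concentration conversion: at a true concentration
#' `C` f/L, uniform deposition over the collection spot puts on average
#' `lambda = C * a * V / A` countable fibers into one microscope field.
#'
#' @param c_true True airborne concentration, f/L (vectorized).
#' @param config A [sampling_config()].
#' @return Expected fiber count per single field (dimensionless).
#' @examples
#' expected_fibers_per_field(3.0) # ~0.99 at the default geometry
#' @export
expected_fibers_per_field <- function(c_true, config = sampling_config()) {
  if (!is.numeric(c_true) || any(is.na(c_true)) || any(c_true < 0)) {
    abort("`c_true` must be non-negative.")
  }
  c_true * config$field_area * config$volume / config$filter_area
}

#' Simulate paired concentration measurements under Poisson counting
#'
#' Models two instruments measuring the same well-mixed aerosol: each draws
#' an independent Poisson total fiber count over its analyzed fields
#' (`N ~ Poisson(lambda * n_fields)` with `lambda` given by
#' [expected_fibers_per_field()]), then converts the count back to a
#' concentration.  All between-method disagreement therefore arises from
#' counting statistics on disjoint filter areas, the stochastic floor of
#' low-count fiber measurements.
#'
#' @param c_true True concentration, f/L.
#' @param n_reps Number of simulated measurement pairs.
#' @param config_x,config_y [sampling_config()] for each method; `config_y`
#'   defaults to `config_x`.
#' @param seed Integer seed; identical seeds give identical series.
#' @return A tibble with columns `rep`, `method_x`, `method_y` (estimated
#'   concentrations, f/L).
#' @examples
#' simulate_paired_series(3, n_reps = 5, seed = 1)
#' @export
simulate_paired_series <- function(c_true, n_reps,
                                   config_x = sampling_config(),
                                   config_y = config_x,
                                   seed = 1L) {
  check_nonneg(c_true, "c_true")
  check_positive(n_reps, "n_reps")
  lam_x <- expected_fibers_per_field(c_true, config_x) * config_x$n_fields
  lam_y <- expected_fibers_per_field(c_true, config_y) * config_y$n_fields
  sfe_x <- fiber_concentration(1, config_x)$single_fiber_equivalent
  sfe_y <- fiber_concentration(1, config_y)$single_fiber_equivalent
  with_seed(seed, {
    tibble(
      rep = seq_len(n_reps),
      method_x = rpois(n_reps, lam_x) * sfe_x,
      method_y = rpois(n_reps, lam_y) * sfe_y
    )
  })
}

#' Limits-of-agreement funnel across concentrations
#'
#' Runs [simulate_paired_series()] and [bland_altman()] at each true
#' concentration in `c_grid` and summarizes how the spread of relative
#' differences widens as the mean number of detected fibers falls — the
#' funnel shape characteristic of Poisson-limited fiber counting.
#'
#' @param c_grid True concentrations to simulate, f/L.
#' @param n_reps Simulated pairs per grid point.
#' @param config_x,config_y Per-method [sampling_config()]s.
#' @param z_mult Limits-of-agreement multiplier.
#' @param seed Integer seed; grid points use derived sub-seeds.
#' @return A tibble of class `loa_funnel`: one row per grid point with
#'   `c_true`, `lambda` (expected count per measurement for method x),
#'   `mean_count` (realized mean detected count), `n_pairs_used`,
#'   `n_excluded`, `mean_rel_diff`, `sd_rel_diff`, `loa_low`, `loa_high`
#'   and `loa_width` (percent).
#' @examples
#' loa_funnel(c(2, 8), n_reps = 200, seed = 3)
#' @export
loa_funnel <- function(c_grid, n_reps = 2000,
                       config_x = sampling_config(),
                       config_y = config_x,
                       z_mult = 1.96, seed = 1L) {
  if (length(c_grid) < 1L) abort("`c_grid` must be non-empty.")
  sfe_x <- fiber_concentration(1, config_x)$single_fiber_equivalent
  rows <- purrr::imap(c_grid, function(c_true, i) {
    series <- simulate_paired_series(
      c_true, n_reps, config_x, config_y,
      seed = seed + 1000L * i
    )
    ba <- bland_altman(relative_differences(series), z_mult = z_mult)
    tibble(
      c_true = c_true,
      lambda = expected_fibers_per_field(c_true, config_x) *
        config_x$n_fields,
      mean_count = mean(series$method_x) / sfe_x,
      n_pairs_used = ba$n_pairs_used,
      n_excluded = ba$n_excluded,
      mean_rel_diff = ba$mean_rel_diff,
      sd_rel_diff = ba$sd_rel_diff,
      loa_low = ba$loa_low,
      loa_high = ba$loa_high,
      loa_width = ba$loa_high - ba$loa_low
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("loa_funnel", class(out))
  out
}

#' Plot the counting-variability funnel
#'
#' Limits-of-agreement width against the mean number of detected fibers,
#' on a log count axis.
#'
#' @param object A `loa_funnel` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loa_funnel <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_count, y = .data$loa_width)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean detected fibers per measurement",
                  y = "Width of 95% limits of agreement (%)") +
    ggplot2::theme_minimal()
}
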