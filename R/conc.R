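#' Sampling configuration for concentration conversion
#'
#' Describes the air-sampling geometry and volume that convert a fiber count
#' on the filter into an airborne concentration: a circular collection spot of
#' diameter `filter_diameter` mm, microscope fields of `field_width` x
#' `field_height` mm, and a sampled volume of `flow_rate * duration` liters.
#' Defaults correspond to a 15-mm collection spot, a 0.66 mm x 0.44 mm field
#' of view, one analyzed field, and 20 min of sampling at 10 L/min (200 L).
#'
#' @param filter_diameter Diameter of the effective (circular) collection
#'   area on the membrane filter, mm.
#' @param field_width,field_height Dimensions of one microscope field of
#'   view, mm.
#' @param flow_rate Sampling pump flow, L/min.
#' @param duration Sampling duration, min.
#' @param n_fields Number of fields of view counted.
#'
#' @return An object of class `sampling_config`: a list with the inputs plus
#'   the derived quantities `filter_area` (mm^2), `field_area` (mm^2) and
#'   `volume` (L).
#' @examples
#' cfg <- sampling_config()
#' cfg$volume # 200 L
#' @export
sampling_config <- function(filter_diameter = 15, field_width = 0.66,
                            field_height = 0.44, flow_rate = 10,
                            duration = 20, n_fields = 1) {
  check_positive(filter_diameter, "filter_diameter")
  check_positive(field_width, "field_width")
  check_positive(field_height, "field_height")
  check_positive(flow_rate, "flow_rate")
  check_positive(duration, "duration")
  check_positive(n_fields, "n_fields")
  structure(
    list(
      filter_diameter = filter_diameter,
      field_width = field_width,
      field_height = field_height,
      flow_rate = flow_rate,
      duration = duration,
      n_fields = n_fields,
      filter_area = effective_filter_area(filter_diameter),
      field_area = field_width * field_height,
      volume = flow_rate * duration
    ),
    class = "sampling_config"
  )
}

#' @export
print.sampling_config <- function(x, ...) {
  cat("<sampling_config>\n")
  cat(sprintf("  filter: %g mm diameter (A = %.2f mm^2)\n",
              x$filter_diameter, x$filter_area))
  cat(sprintf("  field:  %g x %g mm (a = %.4f mm^2), n = %g\n",
              x$field_width, x$field_height, x$field_area, x$n_fields))
  cat(sprintf("  air:    %g L/min x %g min = %g L\n",
              x$flow_rate, x$duration, x$volume))
  invisible(x)
}

#' Effective filter collection area
#'
#' Area of the circular collection spot, `pi * d^2 / 4`.
#'
#' @param diameter Spot diameter, mm.
#' @return Area in mm^2.
#' @examples
#' effective_filter_area(15) # 176.71
#' @export
effective_filter_area <- function(diameter) {
  check_positive(diameter, "diameter")
  pi * diameter^2 / 4
}

#' Convert a fiber count to an airborne concentration
#'
#' Applies the standard membrane-filter conversion
#' `C = A * N / (a * n * V)` where `A` is the effective filter area, `N` the
#' number of fibers counted over `n` fields of area `a`, and `V` the sampled
#' air volume.  The reported concentration is rounded to one decimal place,
#' matching instrument display conventions; the raw value is retained.
#'
#' @param n_fibers Fiber count(s) `N`; vectorized, one result row per count.
#' @param config A [sampling_config()].
#' @return A tibble of class `concentration_result` with columns `n_fibers`,
#'   `concentration_fl` (f/L, rounded to 1 dp), `concentration_raw` (f/L) and
#'   `single_fiber_equivalent` (f/L per counted fiber, the per-cycle
#'   detection granularity).
#' @examples
#' fiber_concentration(1, sampling_config()) # 3.0 f/L
#' @export
fiber_concentration <- function(n_fibers, config = sampling_config()) {
  stopifnot(inherits(config, "sampling_config"))
  if (!is.numeric(n_fibers) || any(is.na(n_fibers)) || any(n_fibers < 0)) {
    abort("`n_fibers` must be non-negative counts.")
  }
  sfe <- config$filter_area /
    (config$field_area * config$n_fields * config$volume)
  raw <- n_fibers * sfe
  out <- tibble(
    n_fibers = n_fibers,
    concentration_fl = round(raw, 1),
    concentration_raw = raw,
    single_fiber_equivalent = sfe
  )
  class(out) <- c("concentration_result", class(out))
  out
}

#' Fields or volume needed to reach a target detection granularity
#'
#' Finds the smallest integer number of fields (or the smallest sampled
#' volume) such that the single-fiber-equivalent concentration
#' `A / (a * n * V)` falls at or below `target`.  Increasing either the
#' number of analyzed fields or the sampling duration lowers the
#' concentration represented by a single counted fiber.
#'
#' @param target Target single-fiber-equivalent concentration, f/L.
#' @param config A [sampling_config()]; its `n_fields` (or `volume`) is the
#'   quantity being solved for, the other parameters are held fixed.
#' @param vary Which knob to solve for: `"n_fields"` or `"volume"`.
#' @return A one-row tibble with columns `vary`, `value` (the minimal
#'   n_fields or volume in L), and `achieved` (the resulting
#'   single-fiber-equivalent, f/L).
#' @examples
#' required_fields_or_volume(3.1) # one field suffices at defaults
#' @export
required_fields_or_volume <- function(target, config = sampling_config(),
                                      vary = c("n_fields", "volume")) {
  check_positive(target, "target")
  vary <- match.arg(vary)
  A <- config$filter_area
  a <- config$field_area
  if (vary == "n_fields") {
    value <- max(1L, as.integer(ceiling(A / (a * config$volume * target) - 1e-9)))
    achieved <- A / (a * value * config$volume)
  } else {
    value <- A / (a * config$n_fields * target)
    achieved <- A / (a * config$n_fields * value)
  }
  tibble(vary = vary, value = value, achieved = achieved)
}
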